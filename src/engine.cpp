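#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Boundary-driven (Eden) growth on a 2D square lattice with a Moore
// neighborhood. One event = pick an occupied voxel uniformly, attempt
// division into a uniformly chosen empty Moore neighbor, then apply the
// death trial to the SAME chosen voxel (the daughter placed this event is
// not a death candidate this event). Driver mutations arrive Poisson(mu)
// per division under an infinite-sites model; a division acquiring >= 1
// new driver founds a new clone. All randomness comes from R's RNG so that
// set.seed() gives bit-identical trajectories.

// Moore offsets in fixed row-major order for reproducibility.
static const int OFF[8][2] = {
  {-1,-1},{-1,0},{-1,1},{0,-1},{0,1},{1,-1},{1,0},{1,1}
};

struct CloneStats {
  std::vector<double> core, edge, sumdist;
};

// [[Rcpp::export]]
List cpp_run_engine(IntegerMatrix grid,
                    IntegerVector center,       // 1-based (row, col)
                    bool detected,
                    double event_index,
                    double sweep,
                    double sweep_quota,
                    IntegerVector parent,
                    IntegerVector ndrv,
                    NumericVector birth_event,
                    List newmuts,
                    int next_mut_id,
                    List params,
                    double max_events,
                    double max_sweeps,
                    int record_every,
                    bool record_events) {
  RNGScope scope;

  const int nr = grid.nrow(), nc = grid.ncol();
  const double b  = as<double>(params["b"]);
  const double s  = as<double>(params["s"]);
  const double mu = as<double>(params["mu"]);
  const double d1 = as<double>(params["d1"]);
  const double d2 = as<double>(params["d2"]);
  const double R  = as<double>(params["R"]);
  const double det_radius = as<double>(params["detection_radius"]);
  const double max_voxels = as<double>(params["max_voxels"]);
  const bool quiescent = as<std::string>(params["growth_variant"]) == "quiescent";
  const bool sel_death = as<std::string>(params["selection_variant"]) == "death";
  const double det_thresh = std::ceil(M_PI * det_radius * det_radius);
  const double R2 = R * R + 1e-9;  // ties (distance exactly R) belong to the core
  const int ci = center[0] - 1, cj = center[1] - 1;

  // ledger copied into growable vectors
  std::vector<int> v_parent(parent.begin(), parent.end());
  std::vector<int> v_ndrv(ndrv.begin(), ndrv.end());
  std::vector<double> v_birth(birth_event.begin(), birth_event.end());
  std::vector< std::vector<int> > v_muts;
  v_muts.reserve(newmuts.size());
  for (int i = 0; i < newmuts.size(); ++i) {
    IntegerVector mi = newmuts[i];
    v_muts.push_back(std::vector<int>(mi.begin(), mi.end()));
  }
  int nclones = (int) v_parent.size();

  // occupied-voxel list with O(1) removal; per-clone regional census
  std::vector<int> occ;
  std::vector<int> where(nr * nc, -1);
  CloneStats cs;
  cs.core.assign(nclones, 0.0);
  cs.edge.assign(nclones, 0.0);
  cs.sumdist.assign(nclones, 0.0);
  double m = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int cid = grid(i, j);
      if (cid > 0) {
        if (cid > nclones) stop("grid references clone id %d not in ledger", cid);
        int lin = i + j * nr;
        where[lin] = (int) occ.size();
        occ.push_back(lin);
        double dr = i - ci, dc = j - cj;
        double q2 = dr * dr + dc * dc;
        if (q2 <= R2) cs.core[cid - 1] += 1; else cs.edge[cid - 1] += 1;
        cs.sumdist[cid - 1] += std::sqrt(q2);
        m += 1;
      }
    }
  }

  double detection_event = NA_REAL, detection_sweep = NA_REAL;
  if (!detected && m >= det_thresh) {
    detected = true; detection_event = event_index; detection_sweep = sweep;
  }

  // snapshot store
  std::vector<double> snap_sweep, snap_core, snap_edge, snap_sumdist;
  std::vector<int> snap_clone;
  std::vector<double> snap_det;
  auto record_snapshot = [&](double sw) {
    for (int c = 0; c < nclones; ++c) {
      if (cs.core[c] + cs.edge[c] > 0) {
        snap_sweep.push_back(sw);
        snap_clone.push_back(c + 1);
        snap_core.push_back(cs.core[c]);
        snap_edge.push_back(cs.edge[c]);
        snap_sumdist.push_back(cs.sumdist[c]);
        snap_det.push_back(detected ? 1.0 : 0.0);
      }
    }
  };
  bool recording = record_every > 0;
  double last_recorded = -1.0;
  if (recording && event_index == 0) { record_snapshot(sweep); last_recorded = sweep; }

  // event records (single-step / debugging use)
  std::vector<int> ev_clone, ev_daughter_clone, ev_nmut;
  std::vector<int> ev_r, ev_c, ev_dr, ev_dc;
  std::vector<int> ev_divided, ev_died;

  std::string status = "max_events";
  double events_done = 0;
  if (sweep_quota <= 0) sweep_quota = m;

  if (m >= max_voxels) status = "max_voxels";
  else if (m <= 0) status = "extinct";
  else while (true) {
    if (events_done >= max_events) { status = "max_events"; break; }
    if (sweep >= max_sweeps) { status = "max_sweeps"; break; }

    // pick an occupied voxel uniformly
    int idx = (int) std::floor(unif_rand() * m);
    if (idx >= (int) m) idx = (int) m - 1;
    int lin = occ[idx];
    int pr = lin % nr, pc = lin / nr;
    int cid = grid(pr, pc);
    int n = v_ndrv[cid - 1];

    if (pr == 0 || pr == nr - 1 || pc == 0 || pc == nc - 1) {
      status = "boundary"; break;
    }

    // division attempt
    double pb = sel_death ? b : b * std::pow(1.0 + s, n);
    if (pb > 1.0) pb = 1.0;
    bool divided = false;
    int daughter_clone = NA_INTEGER, nmut = 0, dlin = -1;
    if (unif_rand() < pb) {
      int empties[8], k = 0;
      for (int o = 0; o < 8; ++o) {
        int qr = pr + OFF[o][0], qc = pc + OFF[o][1];
        if (grid(qr, qc) == 0) empties[k++] = qr + qc * nr;
      }
      if (k > 0) {
        int pick = (int) std::floor(unif_rand() * k);
        if (pick >= k) pick = k - 1;
        dlin = empties[pick];
        nmut = (int) R::rpois(mu);
        daughter_clone = cid;
        if (nmut > 0) {
          std::vector<int> ids(nmut);
          for (int t = 0; t < nmut; ++t) ids[t] = next_mut_id++;
          v_parent.push_back(cid);
          v_ndrv.push_back(n + nmut);
          v_birth.push_back(event_index);
          v_muts.push_back(ids);
          nclones++;
          cs.core.push_back(0.0); cs.edge.push_back(0.0); cs.sumdist.push_back(0.0);
          daughter_clone = nclones;
        }
        int qr = dlin % nr, qc = dlin / nr;
        grid(qr, qc) = daughter_clone;
        where[dlin] = (int) occ.size();
        occ.push_back(dlin);
        double dr = qr - ci, dc = qc - cj;
        double q2 = dr * dr + dc * dc;
        if (q2 <= R2) cs.core[daughter_clone - 1] += 1; else cs.edge[daughter_clone - 1] += 1;
        cs.sumdist[daughter_clone - 1] += std::sqrt(q2);
        m += 1;
        divided = true;
        if (qr == 0 || qr == nr - 1 || qc == 0 || qc == nc - 1) {
          status = "boundary"; break;
        }
      }
    }

    // death trial on the chosen cell (regional rate; pre-detection all d1)
    double dr0 = pr - ci, dc0 = pc - cj;
    double q20 = dr0 * dr0 + dc0 * dc0;
    double d = (!detected || q20 <= R2) ? d1 : d2;
    if (sel_death) d *= std::pow(1.0 - s, n);
    bool can_die = true;
    if (quiescent) {
      can_die = false;  // fully surrounded cells are quiescent: no death
      for (int o = 0; o < 8; ++o) {
        int qr = pr + OFF[o][0], qc = pc + OFF[o][1];
        if (grid(qr, qc) == 0) { can_die = true; break; }
      }
    }
    bool died = false;
    if (can_die && unif_rand() < d) {
      grid(pr, pc) = 0;
      int li = where[lin];
      int last = (int) occ.size() - 1;
      occ[li] = occ[last];
      where[occ[last]] = li;
      occ.pop_back();
      where[lin] = -1;
      if (q20 <= R2) cs.core[cid - 1] -= 1; else cs.edge[cid - 1] -= 1;
      cs.sumdist[cid - 1] -= std::sqrt(q20);
      m -= 1;
      died = true;
    }

    event_index += 1;
    events_done += 1;

    if (record_events) {
      ev_r.push_back(pr + 1); ev_c.push_back(pc + 1);
      ev_clone.push_back(cid);
      ev_divided.push_back(divided ? 1 : 0);
      ev_dr.push_back(divided ? (dlin % nr) + 1 : NA_INTEGER);
      ev_dc.push_back(divided ? (dlin / nr) + 1 : NA_INTEGER);
      ev_daughter_clone.push_back(divided ? daughter_clone : NA_INTEGER);
      ev_nmut.push_back(nmut);
      ev_died.push_back(died ? 1 : 0);
    }

    if (!detected && m >= det_thresh) {
      detected = true; detection_event = event_index; detection_sweep = sweep;
    }

    sweep_quota -= 1;
    if (sweep_quota <= 0) {
      sweep += 1;
      sweep_quota = m;
      if (recording && ((long long) sweep) % record_every == 0 && m > 0) {
        record_snapshot(sweep); last_recorded = sweep;
      }
    }

    if (m <= 0) { status = "extinct"; break; }
    if (m >= max_voxels) { status = "max_voxels"; break; }
  }

  if (recording && m > 0 && sweep != last_recorded) record_snapshot(sweep);

  List ledger_out = List::create(
    _["parent"] = wrap(v_parent),
    _["ndrv"] = wrap(v_ndrv),
    _["birth_event"] = wrap(v_birth),
    _["newmuts"] = wrap(v_muts));

  DataFrame snaps = DataFrame::create(
    _["sweep"] = wrap(snap_sweep),
    _["clone_id"] = wrap(snap_clone),
    _["core"] = wrap(snap_core),
    _["edge"] = wrap(snap_edge),
    _["sum_dist"] = wrap(snap_sumdist),
    _["detected"] = wrap(snap_det));

  List events = R_NilValue;
  if (record_events) {
    events = DataFrame::create(
      _["row"] = wrap(ev_r), _["col"] = wrap(ev_c),
      _["clone_id"] = wrap(ev_clone),
      _["divided"] = wrap(ev_divided),
      _["daughter_row"] = wrap(ev_dr), _["daughter_col"] = wrap(ev_dc),
      _["daughter_clone"] = wrap(ev_daughter_clone),
      _["n_new_mutations"] = wrap(ev_nmut),
      _["died"] = wrap(ev_died));
  }

  return List::create(
    _["grid"] = grid,
    _["detected"] = detected,
    _["detection_event"] = detection_event,
    _["detection_sweep"] = detection_sweep,
    _["event_index"] = event_index,
    _["sweep"] = sweep,
    _["sweep_quota"] = sweep_quota,
    _["occupied"] = m,
    _["status"] = status,
    _["ledger"] = ledger_out,
    _["next_mut_id"] = next_mut_id,
    _["snapshots"] = snaps,
    _["events"] = events);
}
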