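#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Event-driven (Gillespie) simulation of a two-state branching process.
// States: 0 = drug-susceptible (S), 1 = primed (P).
// Each cell divides at rate r_state and dies at rate d_state. Under
// switch_mode 0 (division-coupled) each daughter independently switches
// state with probability p_on (S mother) or p_off (P mother); under
// switch_mode 1 (continuous) switching is an independent per-cell event at
// rate 2*p_on*r_s (S) and 2*p_off*r_p (P), the per-time equivalent of the
// per-daughter convention.
// gamma couples S->P switching to the lineage's current primed fraction:
// p_on_eff = p_on * (1 + gamma * primed_fraction_of_lineage).
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
List sim_twostate_cpp(IntegerVector founder_states,
                      IntegerVector founder_lineages,
                      double r_s, double r_p, double d_s, double d_p,
                      double p_on, double p_off, double gamma,
                      double duration, int max_cells, int switch_mode) {
  int n0 = founder_states.size();
  int n_lin = 0;
  for (int i = 0; i < n0; ++i)
    if (founder_lineages[i] > n_lin) n_lin = founder_lineages[i];

  std::vector<int> state(n0), lineage(n0);
  std::vector<double> birth(n0, 0.0);
  std::vector<char> alive(n0, 1);
  std::vector<int> cells_s, cells_p;
  std::vector<int> cntS(n_lin + 1, 0), cntP(n_lin + 1, 0);
  cells_s.reserve(2 * n0);
  cells_p.reserve(2 * n0);

  for (int i = 0; i < n0; ++i) {
    state[i] = founder_states[i];
    lineage[i] = founder_lineages[i];
    if (state[i] == 0) { cells_s.push_back(i); cntS[lineage[i]]++; }
    else               { cells_p.push_back(i); cntP[lineage[i]]++; }
  }

  long div_s = 0, div_p = 0, die_s = 0, die_p = 0, sw_on = 0, sw_off = 0;
  double t = 0.0;
  bool extinct = false, truncated = false;
  double kon_t = 2.0 * p_on * r_s;   // continuous-mode per-cell rates
  double koff_t = 2.0 * p_off * r_p;

  while (true) {
    int nS = (int)cells_s.size(), nP = (int)cells_p.size();
    if (nS + nP == 0) { extinct = true; break; }
    if (nS + nP >= max_cells) { truncated = true; break; }

    double rds = nS * r_s, rxs = nS * d_s, rdp = nP * r_p, rxp = nP * d_p;
    double rss = (switch_mode == 1) ? nS * kon_t : 0.0;
    double rsp = (switch_mode == 1) ? nP * koff_t : 0.0;
    double R = rds + rxs + rdp + rxp + rss + rsp;
    if (R <= 0.0) break;  // static population

    t += exp_rand() / R;
    if (t >= duration) { t = duration; break; }

    double u = unif_rand() * R;  // uniform in [0, R)
    if (u < rds) {
      // S division
      int pos = (int)R_unif_index((double)nS);
      int c = cells_s[pos];
      int l = lineage[c];
      double pe = p_on;
      if (switch_mode == 0) {
        if (gamma > 0.0) {
          double tot = cntS[l] + cntP[l];
          double fr = (tot > 0) ? cntP[l] / tot : 0.0;
          pe = p_on * (1.0 + gamma * fr);
          if (pe > 1.0) pe = 1.0;
        }
      } else pe = 0.0;  // continuous mode: no division-coupled switching
      int d1 = (unif_rand() < pe) ? 1 : 0;
      int d2 = (unif_rand() < pe) ? 1 : 0;
      div_s++;
      sw_on += d1 + d2;
      // daughter 1 reuses the mother's slot
      birth[c] = t;
      if (d1 == 1) {
        cells_s[pos] = cells_s.back(); cells_s.pop_back();
        cells_p.push_back(c);
        state[c] = 1; cntS[l]--; cntP[l]++;
      }
      // daughter 2 is a new cell
      int m = (int)state.size();
      state.push_back(d2); lineage.push_back(l); birth.push_back(t);
      alive.push_back(1);
      if (d2 == 1) { cells_p.push_back(m); cntP[l]++; }
      else         { cells_s.push_back(m); cntS[l]++; }
    } else if (u < rds + rxs) {
      // S death
      int pos = (int)R_unif_index((double)nS);
      int c = cells_s[pos];
      cells_s[pos] = cells_s.back(); cells_s.pop_back();
      alive[c] = 0; cntS[lineage[c]]--;
      die_s++;
    } else if (u < rds + rxs + rdp) {
      // P division
      int pos = (int)R_unif_index((double)nP);
      int c = cells_p[pos];
      int l = lineage[c];
      double pe = (switch_mode == 0) ? p_off : 0.0;
      int d1 = (unif_rand() < pe) ? 0 : 1;
      int d2 = (unif_rand() < pe) ? 0 : 1;
      div_p++;
      sw_off += (d1 == 0) + (d2 == 0);
      birth[c] = t;
      if (d1 == 0) {
        cells_p[pos] = cells_p.back(); cells_p.pop_back();
        cells_s.push_back(c);
        state[c] = 0; cntP[l]--; cntS[l]++;
      }
      int m = (int)state.size();
      state.push_back(d2); lineage.push_back(l); birth.push_back(t);
      alive.push_back(1);
      if (d2 == 1) { cells_p.push_back(m); cntP[l]++; }
      else         { cells_s.push_back(m); cntS[l]++; }
    } else if (u < rds + rxs + rdp + rxp) {
      // P death
      int pos = (int)R_unif_index((double)nP);
      int c = cells_p[pos];
      cells_p[pos] = cells_p.back(); cells_p.pop_back();
      alive[c] = 0; cntP[lineage[c]]--;
      die_p++;
    } else if (u < rds + rxs + rdp + rxp + rss) {
      // continuous S->P switch
      int pos = (int)R_unif_index((double)nS);
      int c = cells_s[pos];
      cells_s[pos] = cells_s.back(); cells_s.pop_back();
      cells_p.push_back(c);
      state[c] = 1; cntS[lineage[c]]--; cntP[lineage[c]]++;
      sw_on++;
    } else {
      // continuous P->S switch
      int pos = (int)R_unif_index((double)nP);
      int c = cells_p[pos];
      cells_p[pos] = cells_p.back(); cells_p.pop_back();
      cells_s.push_back(c);
      state[c] = 0; cntP[lineage[c]]--; cntS[lineage[c]]++;
      sw_off++;
    }
  }

  int n_alive = (int)(cells_s.size() + cells_p.size());
  IntegerVector out_state(n_alive), out_lineage(n_alive);
  NumericVector out_birth(n_alive);
  int k = 0;
  for (size_t i = 0; i < state.size(); ++i) {
    if (alive[i]) {
      out_state[k] = state[i];
      out_lineage[k] = lineage[i];
      out_birth[k] = birth[i];
      ++k;
    }
  }

  return List::create(
    _["state"] = out_state,
    _["lineage"] = out_lineage,
    _["birth_time"] = out_birth,
    _["time"] = t,
    _["extinct"] = extinct,
    _["truncated"] = truncated,
    _["events"] = IntegerVector::create(
      _["divisions_S"] = (int)div_s, _["divisions_P"] = (int)div_p,
      _["deaths_S"] = (int)die_s, _["deaths_P"] = (int)die_p,
      _["switch_on"] = (int)sw_on, _["switch_off"] = (int)sw_off));
}
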