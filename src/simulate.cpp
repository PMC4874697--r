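// Exact (Gillespie) stochastic simulation of birth-death processes with
// anagenetic state transitions: a full tree recorder and a counts-only
// variant that tracks only per-state lineage counts.  Randomness comes from
// R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct StateRates {
  std::vector<double> lambda, mu, qout;      // per-state totals
  std::vector<std::vector<int>> qcol;        // transition targets
  std::vector<std::vector<double>> qval;     // transition rates
  int n;
  double total(int s) const { return lambda[s] + mu[s] + qout[s]; }
};

StateRates make_rates(const NumericVector& lambda, const NumericVector& mu,
                      const NumericMatrix& Q) {
  StateRates r;
  r.n = lambda.size();
  r.lambda.assign(lambda.begin(), lambda.end());
  r.mu.assign(mu.begin(), mu.end());
  r.qout.assign(r.n, 0.0);
  r.qcol.resize(r.n);
  r.qval.resize(r.n);
  for (int i = 0; i < r.n; ++i) {
    for (int j = 0; j < r.n; ++j) {
      if (j == i) continue;
      double q = Q(i, j);
      if (q > 0.0) {
        r.qcol[i].push_back(j);
        r.qval[i].push_back(q);
        r.qout[i] += q;
      }
    }
  }
  return r;
}

}  // namespace

// Full-tree simulator.  Each lineage is an edge from its birth time to the
// time it speciates (2 children), goes extinct, or reaches `duration`.
//' @noRd
// [[Rcpp::export]]
List sim_tree_cpp(NumericVector lambda, NumericVector mu, NumericMatrix Q,
                  int root_state, double duration, int max_lineages) {
  StateRates R = make_rates(lambda, mu, Q);
  const int n = R.n;

  std::vector<int> parent{0};       // 1-based, 0 = none
  std::vector<double> t_start{0.0};
  std::vector<double> t_end{NA_REAL};
  std::vector<int> n_children{0};
  std::vector<int> state{root_state};
  std::vector<bool> alive{false};   // set at the end for survivors

  // living lineages grouped by state for O(1) event attribution
  std::vector<std::vector<int>> members(n);
  std::vector<int> pos_in_members{0};  // index of lineage within its group
  members[root_state].push_back(0);

  long n_living = 1;
  double t = 0.0;
  bool truncated = false;

  auto remove_living = [&](int id) {
    int s = state[id];
    int pos = pos_in_members[id];
    int last = members[s].back();
    members[s][pos] = last;
    pos_in_members[last] = pos;
    members[s].pop_back();
  };

  while (n_living > 0) {
    double total_rate = 0.0;
    for (int s = 0; s < n; ++s)
      total_rate += members[s].size() * R.total(s);
    if (total_rate <= 0.0) break;  // nothing can ever happen again
    t += R::rexp(1.0 / total_rate);
    if (t >= duration) break;

    // pick state, then lineage, then event type
    double u = R::runif(0.0, total_rate);
    int s = n - 1;
    for (int i = 0; i < n; ++i) {
      double block = members[i].size() * R.total(i);
      if (u < block) { s = i; break; }
      u -= block;
    }
    int idx = (int)std::floor(R::runif(0.0, (double)members[s].size()));
    if (idx >= (int)members[s].size()) idx = members[s].size() - 1;
    int id = members[s][idx];

    double v = R::runif(0.0, R.total(s));
    if (v < R.lambda[s]) {
      // speciation: lineage ends, two children begin
      remove_living(id);
      t_end[id] = t;
      n_children[id] = 2;
      for (int c = 0; c < 2; ++c) {
        parent.push_back(id + 1);
        t_start.push_back(t);
        t_end.push_back(NA_REAL);
        n_children.push_back(0);
        state.push_back(s);
        alive.push_back(false);
        pos_in_members.push_back((int)members[s].size());
        members[s].push_back((int)parent.size() - 1);
      }
      ++n_living;
      if (n_living > max_lineages) { truncated = true; break; }
    } else if (v < R.lambda[s] + R.mu[s]) {
      // extinction
      remove_living(id);
      t_end[id] = t;
      --n_living;
    } else {
      // transition along a hypercube edge
      double w = v - R.lambda[s] - R.mu[s];
      int j = R.qcol[s].back();
      for (size_t k = 0; k < R.qcol[s].size(); ++k) {
        if (w < R.qval[s][k]) { j = R.qcol[s][k]; break; }
        w -= R.qval[s][k];
      }
      remove_living(id);
      state[id] = j;
      pos_in_members[id] = (int)members[j].size();
      members[j].push_back(id);
    }
  }

  // close surviving lineages at the horizon (or at the truncation time)
  double t_stop = truncated ? t : duration;
  for (int s = 0; s < n; ++s) {
    for (int id : members[s]) {
      t_end[id] = t_stop;
      alive[id] = true;
    }
  }

  int n_lin = (int)parent.size();
  IntegerVector out_parent(n_lin), out_children(n_lin), out_state(n_lin);
  NumericVector out_t0(n_lin), out_t1(n_lin);
  LogicalVector out_alive(n_lin);
  for (int i = 0; i < n_lin; ++i) {
    out_parent[i] = parent[i];
    out_children[i] = n_children[i];
    out_state[i] = state[i];
    out_t0[i] = t_start[i];
    out_t1[i] = t_end[i];
    out_alive[i] = alive[i];
  }
  return List::create(
      _["parent"] = out_parent, _["t_start"] = out_t0, _["t_end"] = out_t1,
      _["n_children"] = out_children, _["state"] = out_state,
      _["alive"] = out_alive, _["n_extant"] = (int)n_living,
      _["extinct"] = n_living == 0, _["truncated"] = truncated,
      _["t_stop"] = t_stop);
}

// Counts-only simulator: Markov jump process on the per-state lineage count
// vector, recording the counts on a fixed time grid.
//' @noRd
// [[Rcpp::export]]
List sim_counts_cpp(NumericVector lambda, NumericVector mu, NumericMatrix Q,
                    int root_state, double duration, double record_interval,
                    double max_total, bool thin_at_cap) {
  StateRates R = make_rates(lambda, mu, Q);
  const int n = R.n;
  const int n_rec = (int)std::floor(duration / record_interval + 1e-9) + 1;

  std::vector<double> cnt(n, 0.0);
  cnt[root_state] = 1.0;
  double total = 1.0;
  double log_scale = 0.0;  // log of the cumulative thinning correction
  int n_thins = 0;

  NumericMatrix rec(n_rec, n);
  NumericVector rec_times(n_rec), rec_log_scale(n_rec);
  for (int g = 0; g < n_rec; ++g) rec_times[g] = g * record_interval;
  NumericVector first_origin(n, NA_REAL);
  first_origin[root_state] = 0.0;

  int g = 0;  // next grid index to record
  double t = 0.0;
  bool truncated = false;

  while (true) {
    double total_rate = 0.0;
    for (int s = 0; s < n; ++s) total_rate += cnt[s] * R.total(s);
    double t_next = (total_rate > 0.0) ? t + R::rexp(1.0 / total_rate)
                                       : duration + 1.0;
    // record all grid points passed before the event
    while (g < n_rec && rec_times[g] <= t_next + 1e-12 &&
           rec_times[g] <= duration + 1e-12) {
      for (int s = 0; s < n; ++s) rec(g, s) = cnt[s];
      rec_log_scale[g] = log_scale;
      ++g;
    }
    if (t_next >= duration || total <= 0.0 || total_rate <= 0.0) {
      t = duration;
      break;
    }
    t = t_next;

    double u = R::runif(0.0, total_rate);
    int s = n - 1;
    for (int i = 0; i < n; ++i) {
      double block = cnt[i] * R.total(i);
      if (u < block) { s = i; break; }
      u -= block;
    }
    double v = R::runif(0.0, R.total(s));
    if (v < R.lambda[s]) {
      cnt[s] += 1.0;
      total += 1.0;
      if (total >= max_total) {
        if (thin_at_cap) {
          // binomial thinning by 1/2: the expected per-state counts (and
          // hence the frequency dynamics) are preserved, while the realized
          // population stays bounded; record the correction factor
          total = 0.0;
          for (int i2 = 0; i2 < n; ++i2) {
            cnt[i2] = R::rbinom(cnt[i2], 0.5);
            total += cnt[i2];
          }
          log_scale += std::log(2.0);
          ++n_thins;
          if (total <= 0.0) continue;  // extinct by thinning; loop exits
        } else {
          truncated = true;
          break;
        }
      }
    } else if (v < R.lambda[s] + R.mu[s]) {
      cnt[s] -= 1.0;
      total -= 1.0;
      // on total extinction the next pass records zeros on the rest of the
      // grid and exits via the total_rate == 0 branch
    } else {
      double w = v - R.lambda[s] - R.mu[s];
      int j = R.qcol[s].back();
      for (size_t k = 0; k < R.qcol[s].size(); ++k) {
        if (w < R.qval[s][k]) { j = R.qcol[s][k]; break; }
        w -= R.qval[s][k];
      }
      cnt[s] -= 1.0;
      cnt[j] += 1.0;
      if (NumericVector::is_na(first_origin[j])) first_origin[j] = t;
    }
  }

  // unreached grid points stay NA
  for (int gg = g; gg < n_rec; ++gg) {
    for (int s = 0; s < n; ++s) rec(gg, s) = NA_REAL;
    rec_log_scale[gg] = NA_REAL;
  }

  NumericVector final_counts(n);
  for (int s = 0; s < n; ++s) final_counts[s] = cnt[s];
  return List::create(
      _["times"] = rec_times, _["counts"] = rec,
      _["log_scale"] = rec_log_scale,
      _["first_origin"] = first_origin, _["final_counts"] = final_counts,
      _["final_time"] = t, _["extinct"] = total <= 0.0,
      _["truncated"] = truncated, _["n_thins"] = n_thins);
}
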