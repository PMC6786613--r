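#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Optimized full-run simulation engine. Uses R's RNG (unif_rand) with the
// same draw protocol as the R reference engine in engine-reference.R, and
// the same floating-point expression order, so that for identical seeds the
// two engines produce bit-identical runs. Any change to the draw protocol
// here must be mirrored there.

// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List params,
                 bool shift_enabled, double shift_high, int shift_trigger,
                 bool record_series) {
  const int n = as<int>(params["n_households"]);
  const double initial_herd = as<double>(params["initial_herd"]);
  const double g = as<double>(params["growth_rate"]);
  const double dis_p = as<double>(params["disaster_prob"]);
  const double dis_intensity = as<double>(params["disaster_intensity"]);
  const bool uniform_intensity = as<bool>(params["uniform_intensity"]);
  const double base_capacity = as<double>(params["carrying_capacity"]);
  const double poverty = as<double>(params["poverty_threshold"]);
  const double patron_thr = as<double>(params["patron_threshold"]);
  const double patron_floor = as<double>(params["patron_floor"]);
  const double transfer = as<double>(params["transfer_amount"]);
  const double death_thr = as<double>(params["death_threshold"]);
  const int n_steps = as<int>(params["n_steps"]);
  const bool networks = as<bool>(params["networks"]);
  const bool deaths = as<bool>(params["deaths"]);
  const bool global_dis = as<bool>(params["global_disasters"]);
  const bool round_herds = as<bool>(params["round_herds"]);
  const bool client_patrons = as<bool>(params["client_patrons"]);

  std::vector<double> herd(n, initial_herd);
  std::vector<char> alive(n, 1);
  std::vector<int> patron(n, -1);
  std::vector<int> n_clients(n, 0);
  std::vector<int> formed(n, -1);

  double total = 0.0;
  for (int i = 0; i < n; ++i) total += initial_herd;
  double capacity = base_capacity;
  int n_alive = n;

  // per-step reigning-largest network (for the duration metric)
  std::vector<int> reign_patron(n_steps, -1);
  std::vector<int> reign_formed(n_steps, -1);
  std::vector<int> reign_size(n_steps, 0);

  // scratch buffers reused across steps
  std::vector<int> ids; ids.reserve(n);
  std::vector<double> u; u.reserve(n);
  std::vector<int> perm; perm.reserve(n);
  std::vector<int> cand; cand.reserve(n);

  NumericVector s_total, s_growth, s_disloss, s_transfer, s_deathloss, s_capacity;
  IntegerVector s_alive, s_largest;
  if (record_series) {
    s_total = NumericVector(n_steps); s_growth = NumericVector(n_steps);
    s_disloss = NumericVector(n_steps); s_transfer = NumericVector(n_steps);
    s_deathloss = NumericVector(n_steps); s_capacity = NumericVector(n_steps);
    s_alive = IntegerVector(n_steps); s_largest = IntegerVector(n_steps);
  }

  int elevated_steps = 0;

  for (int t = 0; t < n_steps; ++t) {
    double growth_added = 0.0, disaster_loss = 0.0;
    double transfer_moved = 0.0, death_loss = 0.0;

    ids.clear();
    for (int i = 0; i < n; ++i) if (alive[i]) ids.push_back(i);
    const int m = (int) ids.size();

    // 1. growth, in a fresh random visiting order, sequential capacity check
    if (m > 0) {
      u.resize(m); perm.resize(m);
      for (int k = 0; k < m; ++k) { u[k] = unif_rand(); perm[k] = k; }
      std::stable_sort(perm.begin(), perm.end(),
                       [&](int a, int b) { return u[a] < u[b]; });
      for (int k = 0; k < m; ++k) {
        const int i = ids[perm[k]];
        if (total < capacity) {
          double nh = herd[i] * (1.0 + g);
          if (round_herds) nh = std::floor(nh + 0.5);
          growth_added += nh - herd[i];
          total += nh - herd[i];
          herd[i] = nh;
        }
      }
    }

    // 2. disasters, independent per household (id order)
    for (int k = 0; k < m; ++k) {
      const int i = ids[k];
      if (unif_rand() < dis_p) {
        const double intensity = uniform_intensity ? unif_rand() : dis_intensity;
        double nh = herd[i] * (1.0 - intensity);
        if (round_herds) nh = std::floor(nh + 0.5);
        disaster_loss += herd[i] - nh;
        total += nh - herd[i];
        herd[i] = nh;
      }
    }
    if (global_dis && m > 0) {
      if (unif_rand() < dis_p) {
        const double intensity = uniform_intensity ? unif_rand() : dis_intensity;
        for (int k = 0; k < m; ++k) {
          const int i = ids[k];
          double nh = herd[i] * (1.0 - intensity);
          if (round_herds) nh = std::floor(nh + 0.5);
          disaster_loss += herd[i] - nh;
          total += nh - herd[i];
          herd[i] = nh;
        }
      }
    }

    // 3. poverty resolution: patron transfers, new links, deaths
    if (networks && m > 0) {
      u.resize(m); perm.resize(m);
      for (int k = 0; k < m; ++k) { u[k] = unif_rand(); perm[k] = k; }
      std::stable_sort(perm.begin(), perm.end(),
                       [&](int a, int b) { return u[a] < u[b]; });
      for (int k = 0; k < m; ++k) {
        const int i = ids[perm[k]];
        if (!alive[i]) continue;
        if (herd[i] >= poverty) continue;
        if (patron[i] >= 0) {
          const int pat = patron[i];
          if (herd[pat] >= transfer) {
            herd[pat] -= transfer;
            herd[i] += transfer;
            transfer_moved += transfer;
          }
        } else if (n_clients[i] == 0) {
          cand.clear();
          for (int j = 0; j < n; ++j) {
            if (alive[j] && herd[j] > patron_thr && j != i &&
                (client_patrons || patron[j] < 0))
              cand.push_back(j);
          }
          const int nk = (int) cand.size();
          if (nk > 0) {
            int idx = (int) (unif_rand() * nk);
            if (idx >= nk) idx = nk - 1;
            const int j = cand[idx];
            herd[j] -= transfer;
            herd[i] += transfer;
            transfer_moved += transfer;
            patron[i] = j;
            if (n_clients[j] == 0) formed[j] = t + 1;
            n_clients[j] += 1;
          } else if (deaths && herd[i] < death_thr) {
            death_loss += herd[i];
            total -= herd[i];
            herd[i] = 0.0;
            alive[i] = 0;
            --n_alive;
          }
        }
      }
    }

    // 4. patron-floor check (end-of-step)
    if (networks) {
      for (int j = 0; j < n; ++j) {
        if (alive[j] && n_clients[j] > 0 && herd[j] < patron_floor) {
          for (int c = 0; c < n; ++c) if (patron[c] == j) patron[c] = -1;
          n_clients[j] = 0;
          formed[j] = -1;
        }
      }
    }

    // 5. record the reigning largest network
    int best = -1;
    for (int j = 0; j < n; ++j) {
      if (alive[j] && n_clients[j] > 0) {
        if (best < 0 || n_clients[j] > n_clients[best] ||
            (n_clients[j] == n_clients[best] && formed[j] < formed[best]))
          best = j;
      }
    }
    if (best >= 0) {
      reign_patron[t] = best;
      reign_formed[t] = formed[best];
      reign_size[t] = n_clients[best];
    }

    // capacity shift: elevated while any qualifying network exists
    if (shift_enabled) {
      bool qualifying = false;
      for (int j = 0; j < n && !qualifying; ++j)
        if (alive[j] && n_clients[j] >= shift_trigger) qualifying = true;
      capacity = qualifying ? shift_high : base_capacity;
      if (qualifying) ++elevated_steps;
    }

    if (record_series) {
      s_total[t] = total; s_alive[t] = n_alive; s_largest[t] = reign_size[t];
      s_growth[t] = growth_added; s_disloss[t] = disaster_loss;
      s_transfer[t] = transfer_moved; s_deathloss[t] = death_loss;
      s_capacity[t] = capacity;
    }

    // once the population is extinct every remaining step is a no-op that
    // consumes no random draws; the tracker entries stay empty
    if (n_alive == 0) {
      if (record_series) {
        for (int r = t + 1; r < n_steps; ++r) {
          s_total[r] = total;  // residual running total, identical each step
          s_capacity[r] = capacity;
        }
      }
      break;
    }
  }

  // finalize network metrics (same rule as finalize_network_metrics in R)
  int run_max = 0;
  for (int t = 0; t < n_steps; ++t) run_max = std::max(run_max, reign_size[t]);
  int duration = 0;
  if (run_max > 0) {
    int first = 0;
    while (reign_size[first] != run_max) ++first;
    const int pat = reign_patron[first], fstep = reign_formed[first];
    int cur = 0;
    for (int t = 0; t < n_steps; ++t) {
      if (reign_patron[t] == pat && reign_formed[t] == fstep) {
        ++cur;
        duration = std::max(duration, cur);
      } else {
        cur = 0;
      }
    }
  }

  IntegerVector patron_out(n);
  for (int i = 0; i < n; ++i)
    patron_out[i] = patron[i] < 0 ? NA_INTEGER : patron[i] + 1;

  List series = R_NilValue;
  if (record_series) {
    series = List::create(
      _["total"] = s_total, _["alive"] = s_alive, _["largest_size"] = s_largest,
      _["growth"] = s_growth, _["disaster_loss"] = s_disloss,
      _["transfer"] = s_transfer, _["death_loss"] = s_deathloss,
      _["capacity"] = s_capacity);
  }

  return List::create(
    _["herd"] = NumericVector(herd.begin(), herd.end()),
    _["alive"] = LogicalVector(alive.begin(), alive.end()),
    _["patron"] = patron_out,
    _["n_clients"] = IntegerVector(n_clients.begin(), n_clients.end()),
    _["end_population"] = n_alive,
    _["largest_network_size"] = run_max,
    _["largest_network_duration"] = duration,
    _["elevated_steps"] = elevated_steps,
    _["series"] = series,
    _["events"] = List(0));
}
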