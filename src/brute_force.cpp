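#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <functional>

using namespace Rcpp;

// Enumerate all weak compositions of m into J parts, lexicographic.
static void compositions(int m, int J,
                         std::vector<std::vector<int>> &out) {
  std::vector<int> cur(J, 0);
  std::function<void(int, int)> rec = [&](int pos, int rem) {
    if (pos == J - 1) {
      cur[pos] = rem;
      out.push_back(cur);
      return;
    }
    for (int v = 0; v <= rem; ++v) {
      cur[pos] = v;
      rec(pos + 1, rem - v);
    }
  };
  rec(0, m);
}

// Sum over rows of (E - O)^2 / E for one column with total s, where
// E_i = s * m_i / n. A zero-total column (all cells zero) contributes 0,
// the continuous limit of (E - O)^2 / E as E -> 0 with O = 0.
static inline double col_term(const std::vector<double> &m, double n,
                              const int *Ocol, int I, double s) {
  if (s <= 0.0) return 0.0;
  double acc = 0.0;
  for (int i = 0; i < I; ++i) {
    double e = s * m[i] / n;
    double d = e - Ocol[i];
    acc += d * d / e;
  }
  return acc;
}

// Exhaustive max |chi2(D1) - chi2(D2)| over all neighbor pairs (one unit
// moved between two columns within one row). Only moves l -> k with k < l
// are taken: the reverse move is seen when the neighbor itself is
// enumerated, and the absolute difference is symmetric. When skip_zero_cols
// is true, tables with any zero column total (on either side of the pair)
// are excluded from the domain instead of contributing zero-limit terms.
// [[Rcpp::export]]
List bf_sensitivity_cpp(IntegerVector row_margins, int n_cols,
                        bool skip_zero_cols) {
  const int I = row_margins.size();
  const int J = n_cols;
  std::vector<double> m(I);
  double n = 0.0;
  for (int i = 0; i < I; ++i) {
    m[i] = row_margins[i];
    n += m[i];
  }

  std::vector<std::vector<std::vector<int>>> comps(I);
  for (int i = 0; i < I; ++i) compositions(row_margins[i], J, comps[i]);

  // odometer over per-row composition indices
  std::vector<std::size_t> idx(I, 0);
  // table in column-major blocks: O[j*I + i]
  std::vector<int> O(I * J, 0);
  std::vector<int> s(J, 0);
  for (int i = 0; i < I; ++i)
    for (int j = 0; j < J; ++j) {
      O[j * I + i] = comps[i][0][j];
      s[j] += comps[i][0][j];
    }

  double max_delta = 0.0;
  std::uint64_t n_tables = 0, n_valid = 0, n_pairs = 0;
  std::vector<double> ct(J);     // per-column chi2 terms of D1
  std::vector<int> colbuf(I);

  for (;;) {
    ++n_tables;
    bool valid = true;
    if (skip_zero_cols) {
      for (int j = 0; j < J; ++j)
        if (s[j] < 1) { valid = false; break; }
    }

    if (valid) {
      ++n_valid;
      for (int j = 0; j < J; ++j)
        ct[j] = col_term(m, n, &O[j * I], I, (double)s[j]);

      for (int a = 0; a < I; ++a) {
        for (int l = 1; l < J; ++l) {
          if (O[l * I + a] < 1) continue;
          if (skip_zero_cols && s[l] < 2) continue;  // D2 must stay valid
          for (int k = 0; k < l; ++k) {
            // D2: O[a,k] += 1, O[a,l] -= 1
            for (int i = 0; i < I; ++i) colbuf[i] = O[k * I + i];
            colbuf[a] += 1;
            double new_k = col_term(m, n, colbuf.data(), I,
                                    (double)(s[k] + 1));
            for (int i = 0; i < I; ++i) colbuf[i] = O[l * I + i];
            colbuf[a] -= 1;
            double new_l = col_term(m, n, colbuf.data(), I,
                                    (double)(s[l] - 1));
            double delta = std::fabs(new_k + new_l - ct[k] - ct[l]);
            if (delta > max_delta) max_delta = delta;
            ++n_pairs;
          }
        }
      }
    }

    // advance odometer
    int r = 0;
    while (r < I) {
      const std::vector<int> &old = comps[r][idx[r]];
      if (idx[r] + 1 < comps[r].size()) {
        ++idx[r];
        const std::vector<int> &nw = comps[r][idx[r]];
        for (int j = 0; j < J; ++j) {
          s[j] += nw[j] - old[j];
          O[j * I + r] = nw[j];
        }
        break;
      } else {
        idx[r] = 0;
        const std::vector<int> &nw = comps[r][0];
        for (int j = 0; j < J; ++j) {
          s[j] += nw[j] - old[j];
          O[j * I + r] = nw[j];
        }
        ++r;
      }
    }
    if (r == I) break;
  }

  return List::create(_["max_delta"] = max_delta,
                      _["n_tables"] = (double)n_tables,
                      _["n_valid"] = (double)n_valid,
                      _["n_pairs"] = (double)n_pairs);
}
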