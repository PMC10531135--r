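#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

// Iterative run-weighted indel placement followed by uniform substitutions.
//
// Sequences are manipulated as run-length encodings: a deletion shortens the
// chosen homopolymer run by one base and an insertion duplicates the run's
// base inside the run, so runs never split; a run emptied by deletion is
// removed and its neighbours merged when they share a base. Each indel event
// picks a run with probability proportional to length^weight_exp, with
// weights recomputed as runs change. All randomness comes from R's RNG
// (unif_rand), so set.seed() in R makes the whole injection deterministic.
//
// Log encoding: kind 0 = ins, 1 = del, 2 = sub; positions are 1-based and
// refer to the sequence as it stands when the operation is applied (indels)
// or to the post-indel sequence (substitutions), so sequential replay of the
// log on the source sequence reproduces the output exactly.

static inline int base_code(char b) {
  switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline double run_weight(int len, double wexp) {
  if (wexp == 1.0) return (double)len;
  return std::pow((double)len, wexp);
}

// [[Rcpp::export]]
List cpp_inject(CharacterVector sequences, IntegerVector k_ins,
                IntegerVector k_del, IntegerVector k_sub,
                double weight_exp, bool keep_log) {
  int n = sequences.size();
  CharacterVector out(n);
  std::vector<int> log_read, log_kind, log_pos, log_base;

  std::vector<int> run_base, run_len;
  std::vector<double> run_w;
  std::vector<int> idx;

  for (int r = 0; r < n; ++r) {
    std::string seq = as<std::string>(sequences[r]);
    int L = (int)seq.size();
    if (L == 0) stop("read %d has an empty sequence", r + 1);

    // run-length encode
    run_base.clear(); run_len.clear(); run_w.clear();
    double total_w = 0.0;
    long total_len = 0;
    for (int i = 0; i < L; ++i) {
      int b = base_code(seq[i]);
      if (b < 0)
        stop("read %d contains a non-ACGT character at position %d", r + 1, i + 1);
      if (!run_base.empty() && run_base.back() == b) {
        run_len.back() += 1;
      } else {
        run_base.push_back(b);
        run_len.push_back(1);
      }
    }
    for (size_t j = 0; j < run_len.size(); ++j) {
      run_w.push_back(run_weight(run_len[j], weight_exp));
      total_w += run_w.back();
      total_len += run_len[j];
    }

    int rem_ins = k_ins[r], rem_del = k_del[r];
    if (rem_del >= L)
      stop("read %d: %d deletions requested for a %d-base read", r + 1, rem_del, L);

    while (rem_ins + rem_del > 0) {
      bool do_del;
      if (rem_del == 0) do_del = false;
      else if (rem_ins == 0) do_del = true;
      else do_del = unif_rand() < (double)rem_del / (double)(rem_del + rem_ins);

      // weighted run selection with cached weights
      double u = unif_rand() * total_w;
      double acc = 0.0;
      long pos_before = 0;
      size_t chosen = run_len.size() - 1;
      for (size_t j = 0; j < run_len.size(); ++j) {
        acc += run_w[j];
        if (u <= acc) { chosen = j; break; }
        pos_before += run_len[j];
      }
      int start = (int)pos_before + 1;  // 1-based first base of the run
      int b = run_base[chosen];

      if (do_del) {
        if (keep_log) {
          log_read.push_back(r + 1); log_kind.push_back(1);
          log_pos.push_back(start); log_base.push_back(b);
        }
        total_w -= run_w[chosen];
        run_len[chosen] -= 1;
        total_len -= 1;
        if (run_len[chosen] == 0) {
          run_base.erase(run_base.begin() + chosen);
          run_len.erase(run_len.begin() + chosen);
          run_w.erase(run_w.begin() + chosen);
          // merge neighbours that now touch with the same base
          if (chosen > 0 && chosen < run_base.size() &&
              run_base[chosen - 1] == run_base[chosen]) {
            total_w -= run_w[chosen - 1] + run_w[chosen];
            run_len[chosen - 1] += run_len[chosen];
            run_w[chosen - 1] = run_weight(run_len[chosen - 1], weight_exp);
            total_w += run_w[chosen - 1];
            run_base.erase(run_base.begin() + chosen);
            run_len.erase(run_len.begin() + chosen);
            run_w.erase(run_w.begin() + chosen);
          }
        } else {
          run_w[chosen] = run_weight(run_len[chosen], weight_exp);
          total_w += run_w[chosen];
        }
        rem_del--;
      } else {
        if (keep_log) {
          log_read.push_back(r + 1); log_kind.push_back(0);
          log_pos.push_back(start); log_base.push_back(b);
        }
        total_w -= run_w[chosen];
        run_len[chosen] += 1;
        run_w[chosen] = run_weight(run_len[chosen], weight_exp);
        total_w += run_w[chosen];
        total_len += 1;
        rem_ins--;
      }
    }

    // rebuild sequence from runs
    std::string cur;
    cur.reserve(total_len);
    for (size_t j = 0; j < run_base.size(); ++j)
      cur.append(run_len[j], BASES[run_base[j]]);

    // substitutions: distinct uniform positions, base replaced by one of the
    // other three (k capped at the current length)
    int Lc = (int)cur.size();
    int ks = k_sub[r] < Lc ? k_sub[r] : Lc;
    if (ks > 0) {
      idx.resize(Lc);
      for (int i = 0; i < Lc; ++i) idx[i] = i;
      for (int j = 0; j < ks; ++j) {
        int t = j + (int)(unif_rand() * (Lc - j));
        if (t >= Lc) t = Lc - 1;
        std::swap(idx[j], idx[t]);
        int pos = idx[j];
        int old = base_code(cur[pos]);
        int nb = (int)(unif_rand() * 3.0);
        if (nb > 2) nb = 2;
        if (nb >= old) nb += 1;
        cur[pos] = BASES[nb];
        if (keep_log) {
          log_read.push_back(r + 1); log_kind.push_back(2);
          log_pos.push_back(pos + 1); log_base.push_back(nb);
        }
      }
    }

    out[r] = cur;
  }

  List res = List::create(_["sequence"] = out);
  if (keep_log) {
    res["log_read"] = wrap(log_read);
    res["log_kind"] = wrap(log_kind);
    res["log_pos"] = wrap(log_pos);
    res["log_base"] = wrap(log_base);
  }
  return res;
}
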