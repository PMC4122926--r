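// Affine-gap local alignment (Smith-Waterman / Gotoh) with traceback.
// Scoring: a gap of length k costs gap_open + k * gap_extend.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// direction codes for traceback
enum { STOP = 0, DIAG = 1, FROM_E = 2, FROM_F = 3 };
enum { OPEN = 0, EXT = 1 };

// Align one query against many targets.  lookup is a 128 x 128 score
// matrix indexed by ASCII code (query row, target column).  Returns one
// row per target: score, q_start, q_end, t_start, t_end, aln_len,
// n_ident, mismatch, gap_openings (1-based inclusive spans; zeros when no
// positive-scoring alignment exists).
// [[Rcpp::export(name = ".gotoh_batch")]]
NumericMatrix gotoh_batch(std::string query,
                          std::vector<std::string> targets,
                          NumericMatrix lookup,
                          double gap_open, double gap_extend) {
  const int m = query.size();
  const int nt = targets.size();
  NumericMatrix out(nt, 9);
  const double ginit = gap_open + gap_extend;

  std::vector<double> H((m + 1)), E((m + 1));
  for (int ti = 0; ti < nt; ++ti) {
    const std::string& tgt = targets[ti];
    const int n = tgt.size();
    // byte traceback matrices, (m+1) x (n+1)
    std::vector<unsigned char> dH((size_t)(m + 1) * (n + 1), STOP);
    std::vector<unsigned char> dE((size_t)(m + 1) * (n + 1), OPEN);
    std::vector<unsigned char> dF((size_t)(m + 1) * (n + 1), OPEN);
    std::fill(H.begin(), H.end(), 0.0);
    std::fill(E.begin(), E.end(), R_NegInf);
    double best = 0.0; int bi = 0, bj = 0;
    for (int j = 1; j <= n; ++j) {
      double diag_prev = 0.0;      // H[i-1][j-1]
      double Hij_left;             // H[i][j-1] (before overwrite)
      double F = R_NegInf;
      const double* srow = &lookup((unsigned char)0, 0); // unused guard
      (void)srow;
      for (int i = 1; i <= m; ++i) {
        Hij_left = H[i];           // still holds column j-1 value
        // E: gap in target (consumes query? no: E moves along target)
        //    here E[i] tracks gaps in the QUERY direction j (left moves)
        double e_open = Hij_left - ginit;
        double e_ext = E[i] - gap_extend;
        size_t idx = (size_t)i * (n + 1) + j;
        if (e_ext > e_open) { E[i] = e_ext; dE[idx] = EXT; }
        else { E[i] = e_open; dE[idx] = OPEN; }
        // F: up moves (gap in target string)
        double f_open = H[i - 1] - ginit;  // H[i-1][j] current column
        double f_ext = F - gap_extend;
        if (f_ext > f_open) { F = f_ext; dF[idx] = EXT; }
        else { F = f_open; dF[idx] = OPEN; }
        double sc = lookup((unsigned char)query[i - 1],
                           (unsigned char)tgt[j - 1]);
        double h = diag_prev + sc;
        unsigned char dir = DIAG;
        if (E[i] > h) { h = E[i]; dir = FROM_E; }
        if (F > h) { h = F; dir = FROM_F; }
        if (h <= 0.0) { h = 0.0; dir = STOP; }
        dH[idx] = dir;
        diag_prev = H[i];
        H[i] = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    double score = best;
    int q1 = 0, q2 = 0, t1 = 0, t2 = 0;
    int aln_len = 0, n_ident = 0, mism = 0, gapopen = 0;
    if (score > 0.0) {
      // traceback
      int i = bi, j = bj;
      q2 = bi; t2 = bj;
      int state = 0; // 0 = in H
      bool in_gap = false;
      while (true) {
        size_t idx = (size_t)i * (n + 1) + j;
        if (state == 0) {
          unsigned char d = dH[idx];
          if (d == STOP) break;
          if (d == DIAG) {
            ++aln_len;
            if (query[i - 1] == tgt[j - 1]) ++n_ident; else ++mism;
            in_gap = false;
            --i; --j;
          } else if (d == FROM_E) { state = 1; }
          else { state = 2; }
        } else if (state == 1) {   // E: move left (gap in query axis i)
          ++aln_len;
          if (!in_gap) { ++gapopen; in_gap = true; }
          unsigned char d = dE[idx];
          --j;
          if (d == OPEN) { state = 0; in_gap = false; }
        } else {                    // F: move up
          ++aln_len;
          if (!in_gap) { ++gapopen; in_gap = true; }
          unsigned char d = dF[idx];
          --i;
          if (d == OPEN) { state = 0; in_gap = false; }
        }
      }
      q1 = i + 1; t1 = j + 1;
    }
    out(ti, 0) = score; out(ti, 1) = q1; out(ti, 2) = q2;
    out(ti, 3) = t1; out(ti, 4) = t2; out(ti, 5) = aln_len;
    out(ti, 6) = n_ident; out(ti, 7) = mism; out(ti, 8) = gapopen;
  }
  colnames(out) = CharacterVector::create(
    "raw_score", "q_start", "q_end", "t_start", "t_end", "aln_len",
    "n_ident", "mismatch", "gap_openings");
  return out;
}

// Aligned strings for a single pair (for display / records).
// [[Rcpp::export(name = ".gotoh_pair_strings")]]
List gotoh_pair_strings(std::string query, std::string target,
                        NumericMatrix lookup,
                        double gap_open, double gap_extend) {
  const int m = query.size(), n = target.size();
  const double ginit = gap_open + gap_extend;
  std::vector<double> H(m + 1, 0.0), E(m + 1, R_NegInf);
  std::vector<unsigned char> dH((size_t)(m + 1) * (n + 1), STOP);
  std::vector<unsigned char> dE((size_t)(m + 1) * (n + 1), OPEN);
  std::vector<unsigned char> dF((size_t)(m + 1) * (n + 1), OPEN);
  double best = 0.0; int bi = 0, bj = 0;
  for (int j = 1; j <= n; ++j) {
    double diag_prev = 0.0, F = R_NegInf;
    for (int i = 1; i <= m; ++i) {
      size_t idx = (size_t)i * (n + 1) + j;
      double e_open = H[i] - ginit, e_ext = E[i] - gap_extend;
      if (e_ext > e_open) { E[i] = e_ext; dE[idx] = EXT; }
      else { E[i] = e_open; dE[idx] = OPEN; }
      double f_open = H[i - 1] - ginit, f_ext = F - gap_extend;
      if (f_ext > f_open) { F = f_ext; dF[idx] = EXT; }
      else { F = f_open; dF[idx] = OPEN; }
      double h = diag_prev + lookup((unsigned char)query[i - 1],
                                    (unsigned char)target[j - 1]);
      unsigned char dir = DIAG;
      if (E[i] > h) { h = E[i]; dir = FROM_E; }
      if (F > h) { h = F; dir = FROM_F; }
      if (h <= 0.0) { h = 0.0; dir = STOP; }
      dH[idx] = dir;
      diag_prev = H[i]; H[i] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string qa, ta;
  int i = bi, j = bj, state = 0;
  if (best > 0.0) {
    while (true) {
      size_t idx = (size_t)i * (n + 1) + j;
      if (state == 0) {
        unsigned char d = dH[idx];
        if (d == STOP) break;
        if (d == DIAG) { qa += query[i - 1]; ta += target[j - 1]; --i; --j; }
        else if (d == FROM_E) state = 1;
        else state = 2;
      } else if (state == 1) {
        qa += '-'; ta += target[j - 1];
        unsigned char d = dE[idx]; --j;
        if (d == OPEN) state = 0;
      } else {
        qa += query[i - 1]; ta += '-';
        unsigned char d = dF[idx]; --i;
        if (d == OPEN) state = 0;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());
  }
  return List::create(_["score"] = best, _["q_start"] = (best > 0) ? i + 1 : 0,
                      _["t_start"] = (best > 0) ? j + 1 : 0,
                      _["q_end"] = (best > 0) ? bi : 0,
                      _["t_end"] = (best > 0) ? bj : 0,
                      _["q_aln"] = qa, _["t_aln"] = ta);
}
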