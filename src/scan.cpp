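#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive sliding-window scorer for the information-weighted matrix
// similarity score, evaluating several matrices on both strands in one pass.
//
// `mats` holds one list per matrix with elements:
//   fwd, rev : 5 x W contribution tables (columns = positions) where rows
//              0..3 are w[i] * f[i, A/C/G/T] for the forward matrix and its
//              reverse complement, and row 4 is the contribution of an
//              ambiguous base (the position minimum);
//   min_raw  : absolute raw-score threshold (threshold * max_raw);
//   max_raw  : raw score of the consensus, used to normalize.
// `from` / `to` give, per sequence, the 0-based half-open interval of
// absolute positions the match must lie in; valid starts for a width-W
// matrix are from[si] .. to[si] - W (re-clipped to the sequence here).
// [[Rcpp::export]]
List scan_sequences_cpp(CharacterVector seqs, List mats, IntegerVector from,
                        IntegerVector to) {
  const int n_mat = mats.size();
  std::vector<std::vector<double>> fwd(n_mat), rev(n_mat);
  std::vector<double> min_raw(n_mat), max_raw(n_mat);
  std::vector<int> width(n_mat);
  for (int m = 0; m < n_mat; ++m) {
    List mm = mats[m];
    NumericMatrix f = mm["fwd"], r = mm["rev"];
    width[m] = f.ncol();
    fwd[m].assign(f.begin(), f.end());   // column-major, 5 rows
    rev[m].assign(r.begin(), r.end());
    min_raw[m] = as<double>(mm["min_raw"]);
    max_raw[m] = as<double>(mm["max_raw"]);
  }

  std::vector<int> out_seq, out_start, out_strand, out_mat;
  std::vector<double> out_score;
  std::vector<unsigned char> code;

  for (int si = 0; si < seqs.size(); ++si) {
    SEXP el = STRING_ELT(seqs, si);
    const char *s = CHAR(el);
    const int L = LENGTH(el);
    code.resize(L);
    for (int i = 0; i < L; ++i) {
      switch (s[i]) {
        case 'A': code[i] = 0; break;
        case 'C': code[i] = 1; break;
        case 'G': code[i] = 2; break;
        case 'T': code[i] = 3; break;
        default:  code[i] = 4;
      }
    }
    for (int m = 0; m < n_mat; ++m) {
      const int W = width[m];
      const double *cf = fwd[m].data();
      const double *cr = rev[m].data();
      const double thr = min_raw[m], mx = max_raw[m];
      int lo = from[si] < 0 ? 0 : from[si];
      int hi = to[si] - W;
      if (hi > L - W) hi = L - W;
      for (int p = lo; p <= hi; ++p) {
        double sf = 0.0, sr = 0.0;
        const unsigned char *c = &code[p];
        for (int i = 0; i < W; ++i) {
          sf += cf[5 * i + c[i]];
          sr += cr[5 * i + c[i]];
        }
        if (sf >= thr) {
          out_seq.push_back(si + 1); out_start.push_back(p);
          out_strand.push_back(1); out_mat.push_back(m + 1);
          out_score.push_back(sf / mx);
        }
        if (sr >= thr) {
          out_seq.push_back(si + 1); out_start.push_back(p);
          out_strand.push_back(2); out_mat.push_back(m + 1);
          out_score.push_back(sr / mx);
        }
      }
    }
  }
  return List::create(_["seq"] = wrap(out_seq), _["mat"] = wrap(out_mat),
                      _["start"] = wrap(out_start),
                      _["strand"] = wrap(out_strand),
                      _["score"] = wrap(out_score));
}
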