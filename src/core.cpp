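#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Haplotypes are stored loci x gametes (columns are haplotypes, two adjacent
// columns per individual), loci sorted by (chromosome, position).  Positions
// are chromosome-local centimorgans.  All randomness comes from the R RNG so
// that set.seed() governs reproducibility end to end.

static void chrom_ranges(const IntegerVector& chrom,
                         std::vector<int>& starts, std::vector<int>& ends) {
  const int S = chrom.size();
  starts.clear(); ends.clear();
  int i = 0;
  while (i < S) {
    const int c = chrom[i];
    int j = i;
    while (j < S && chrom[j] == c) ++j;
    starts.push_back(i); ends.push_back(j);
    i = j;
  }
}

struct Meiosis {
  int startHap;                 // 0 or 1, fair coin per chromosome
  std::vector<double> bk;       // sorted crossover positions (cM)
};

static void draw_meiosis(double chromLenCm, Meiosis& m) {
  const double morgan = chromLenCm / 100.0;
  const int k = (int) R::rpois(morgan);
  m.startHap = (unif_rand() < 0.5) ? 0 : 1;
  m.bk.resize(k);
  for (int i = 0; i < k; ++i) m.bk[i] = unif_rand() * chromLenCm;
  std::sort(m.bk.begin(), m.bk.end());
}

// copy one recombined chromosome (locus range [s,e)) from parental haplotype
// columns h0/h1 into out, switching source at each crossover
static void apply_meiosis(const int* h0, const int* h1, int* out,
                          const double* pos, int s, int e, const Meiosis& m) {
  int cur = m.startHap;
  const int k = (int) m.bk.size();
  int i = s;
  for (int b = 0; b <= k; ++b) {
    const double upper = (b < k) ? m.bk[b] : R_PosInf;
    int j = i;
    while (j < e && pos[j] < upper) ++j;
    if (j > i)
      std::memcpy(out + i, (cur ? h1 : h0) + i, (size_t)(j - i) * sizeof(int));
    cur = 1 - cur;
    i = j;
    if (i >= e && b + 1 <= k) break;
  }
  if (i < e)  // no crossovers beyond last locus
    std::memcpy(out + i, (cur ? h1 : h0) + i, (size_t)(e - i) * sizeof(int));
}

// Neutral Wright-Fisher burn-in with infinite-alleles mutation.  Starts from a
// monomorphic population (allele 0 everywhere); each mutation creates a novel
// integer allele.  Returns the final 2*ne haplotypes as allele labels.
// [[Rcpp::export]]
IntegerMatrix cpp_wf_burnin(int ne, int nGenerations,
                            IntegerVector chrom, NumericVector pos,
                            NumericVector chromLen, double mu) {
  const int S = chrom.size();
  std::vector<int> cs, ce;
  chrom_ranges(chrom, cs, ce);
  const int H = 2 * ne;
  IntegerMatrix cur(S, H), nxt(S, H);
  int counter = 0;
  const double lambdaMut = mu * (double) S;
  Meiosis m;
  for (int g = 0; g < nGenerations; ++g) {
    for (int ind = 0; ind < ne; ++ind) {
      for (int gam = 0; gam < 2; ++gam) {
        int parent = (int)(unif_rand() * ne);
        if (parent >= ne) parent = ne - 1;
        const int* h0 = &cur(0, 2 * parent);
        const int* h1 = &cur(0, 2 * parent + 1);
        int* out = &nxt(0, 2 * ind + gam);
        for (size_t c = 0; c < cs.size(); ++c) {
          draw_meiosis(chromLen[(int)c], m);
          apply_meiosis(h0, h1, out, REAL(pos), cs[c], ce[c], m);
        }
        const int nm = (int) R::rpois(lambdaMut);
        for (int t = 0; t < nm; ++t) {
          int site = (int)(unif_rand() * S);
          if (site >= S) site = S - 1;
          out[site] = ++counter;
        }
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Collapse infinite-alleles labels to biallelic 0/1 codes: allele 0 is the
// most frequent label at the site (frequency ties broken towards the smaller
// label), allele 1 collects all others.  Monomorphic sites are dropped;
// `freq` is the frequency of allele 1.
// [[Rcpp::export]]
List cpp_collapse_biallelic(IntegerMatrix labs) {
  const int S = labs.nrow(), H = labs.ncol();
  std::vector<int> keep, major;
  std::vector<double> fr;
  keep.reserve(S);
  std::vector<int> buf((size_t) H);
  for (int s = 0; s < S; ++s) {
    for (int h = 0; h < H; ++h) buf[h] = labs(s, h);
    std::sort(buf.begin(), buf.end());
    int bestLab = buf[0], bestCnt = 0;
    int i = 0;
    bool poly = false;
    while (i < H) {
      int j = i;
      while (j < H && buf[j] == buf[i]) ++j;
      if (j - i > bestCnt) { bestCnt = j - i; bestLab = buf[i]; }
      if (i > 0) poly = true;
      i = j;
    }
    if (!poly) continue;
    keep.push_back(s);
    major.push_back(bestLab);
    fr.push_back(1.0 - (double) bestCnt / (double) H);
  }
  const int K = (int) keep.size();
  IntegerMatrix out(K, H);
  NumericVector freq(K);
  IntegerVector idx(K);
  for (int k = 0; k < K; ++k) {
    const int s = keep[k];
    idx[k] = s + 1;
    freq[k] = fr[(size_t) k];
    for (int h = 0; h < H; ++h)
      out(k, h) = (labs(s, h) == major[(size_t) k]) ? 0 : 1;
  }
  return List::create(_["idx"] = idx, _["alleles"] = out, _["freq"] = freq);
}

// One gamete per entry of `parent` (1-based individual index).  The allele and
// founder-label tracks are recombined with identical breakpoints.
// [[Rcpp::export]]
List cpp_make_gametes(IntegerMatrix alleles, IntegerMatrix labels,
                      IntegerVector parent,
                      IntegerVector chrom, NumericVector pos,
                      NumericVector chromLen) {
  const int S = chrom.size();
  const int G = parent.size();
  std::vector<int> cs, ce;
  chrom_ranges(chrom, cs, ce);
  IntegerMatrix outA(S, G), outL(S, G);
  Meiosis m;
  for (int g = 0; g < G; ++g) {
    const int p = parent[g] - 1;
    const int* a0 = &alleles(0, 2 * p);
    const int* a1 = &alleles(0, 2 * p + 1);
    const int* l0 = &labels(0, 2 * p);
    const int* l1 = &labels(0, 2 * p + 1);
    int* oa = &outA(0, g);
    int* ol = &outL(0, g);
    for (size_t c = 0; c < cs.size(); ++c) {
      draw_meiosis(chromLen[(int)c], m);
      apply_meiosis(a0, a1, oa, REAL(pos), cs[c], ce[c], m);
      apply_meiosis(l0, l1, ol, REAL(pos), cs[c], ce[c], m);
    }
  }
  return List::create(_["alleles"] = outA, _["labels"] = outL);
}

// in-place write of A into columns [startCol, ...) of the preallocated
// buffer M (1-based startCol); M is owned by the caller's growth buffer
// [[Rcpp::export]]
void cpp_write_cols(IntegerMatrix M, int startCol, IntegerMatrix A) {
  const int S = M.nrow();
  if (A.nrow() != S) stop("row mismatch");
  if (startCol - 1 + A.ncol() > M.ncol()) stop("buffer overflow");
  std::memcpy(&M(0, startCol - 1), &A(0, 0),
              (size_t) S * A.ncol() * sizeof(int));
}

// fast column concatenation of two integer matrices (plain memcpy)
// [[Rcpp::export]]
IntegerMatrix cpp_cbind_int(IntegerMatrix A, IntegerMatrix B) {
  const int S = A.nrow();
  if (B.nrow() != S) stop("row mismatch");
  IntegerMatrix out(S, A.ncol() + B.ncol());
  std::memcpy(&out(0, 0), &A(0, 0), (size_t) S * A.ncol() * sizeof(int));
  std::memcpy(&out(0, A.ncol()), &B(0, 0),
              (size_t) S * B.ncol() * sizeof(int));
  return out;
}

static inline double match_frac(const int* x, const int* y, int S) {
  int c = 0;
  for (int i = 0; i < S; ++i) c += (x[i] == y[i]);
  return (double) c / (double) S;
}

// True IBD relationship matrix from founder-origin labels (loci x 2N).
// Diagonal: 1 + fraction of loci with two identical labels.  Off-diagonal:
// mean identity fraction over the four gamete combinations, times 2 / 2.
// [[Rcpp::export]]
NumericMatrix cpp_ibd_matrix(IntegerMatrix labels) {
  const int S = labels.nrow();
  const int N = labels.ncol() / 2;
  NumericMatrix Gm(N, N);
  for (int a = 0; a < N; ++a) {
    const int* a1 = &labels(0, 2 * a);
    const int* a2 = &labels(0, 2 * a + 1);
    Gm(a, a) = 1.0 + match_frac(a1, a2, S);
    for (int b = a + 1; b < N; ++b) {
      const int* b1 = &labels(0, 2 * b);
      const int* b2 = &labels(0, 2 * b + 1);
      const double v = 0.5 * (match_frac(a1, b1, S) + match_frac(a1, b2, S) +
                              match_frac(a2, b1, S) + match_frac(a2, b2, S));
      Gm(a, b) = v;
      Gm(b, a) = v;
    }
  }
  return Gm;
}

// Per-individual fraction of loci with identical founder labels (F_IBD).
// [[Rcpp::export]]
NumericVector cpp_ibd_inbreeding(IntegerMatrix labels) {
  const int S = labels.nrow();
  const int N = labels.ncol() / 2;
  NumericVector f(N);
  for (int a = 0; a < N; ++a)
    f[a] = match_frac(&labels(0, 2 * a), &labels(0, 2 * a + 1), S);
  return f;
}

// Maximal runs of identical alleles between two haplotypes, per chromosome,
// kept iff they span >= minSnps loci and >= minLen cM (positions of first and
// last locus of the run define the half-open [start, end) interval).
static void scan_pair(const int* x, const int* y,
                      const IntegerVector& chrom, const double* pos,
                      const std::vector<int>& cs, const std::vector<int>& ce,
                      int minSnps, double minLen,
                      std::vector<double>& rows, double ia, double ha,
                      double ib, double hb) {
  for (size_t c = 0; c < cs.size(); ++c) {
    int i = cs[c];
    const int e = ce[c];
    while (i < e) {
      if (x[i] != y[i]) { ++i; continue; }
      int j = i;
      while (j < e && x[j] == y[j]) ++j;
      const int n = j - i;
      const double span = pos[j - 1] - pos[i];
      if (n >= minSnps && span >= minLen) {
        rows.push_back(ia); rows.push_back(ha);
        rows.push_back(ib); rows.push_back(hb);
        rows.push_back((double) chrom[i]);
        rows.push_back(pos[i]);
        rows.push_back(pos[j - 1]);
        rows.push_back((double) n);
      }
      i = j;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_shared_segments(IntegerVector hapA, IntegerVector hapB,
                                  IntegerVector chrom, NumericVector pos,
                                  int minSnps, double minLen) {
  std::vector<int> cs, ce;
  chrom_ranges(chrom, cs, ce);
  std::vector<double> rows;
  scan_pair(hapA.begin(), hapB.begin(), chrom, REAL(pos), cs, ce,
            minSnps, minLen, rows, 0, 0, 0, 0);
  const int n = (int)(rows.size() / 8);
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = rows[8 * i + 4];
    out(i, 1) = rows[8 * i + 5];
    out(i, 2) = rows[8 * i + 6];
    out(i, 3) = rows[8 * i + 7];
  }
  colnames(out) = CharacterVector::create("chrom", "startCm", "endCm", "nSnps");
  return out;
}

// All within-individual (a1,a2) pairs plus the four cross combinations for
// every unordered pair a < b.  Columns: indivA, hapA, indivB, hapB, chrom,
// startCm, endCm, nSnps (individuals as 1-based indices into the input).
// [[Rcpp::export]]
NumericMatrix cpp_collect_segments(IntegerMatrix haps,
                                   IntegerVector chrom, NumericVector pos,
                                   int minSnps, double minLen) {
  const int N = haps.ncol() / 2;
  std::vector<int> cs, ce;
  chrom_ranges(chrom, cs, ce);
  const double* p = REAL(pos);
  std::vector<double> rows;
  for (int a = 0; a < N; ++a) {
    const int* a1 = &haps(0, 2 * a);
    const int* a2 = &haps(0, 2 * a + 1);
    scan_pair(a1, a2, chrom, p, cs, ce, minSnps, minLen, rows,
              a + 1, 1, a + 1, 2);
    for (int b = a + 1; b < N; ++b) {
      const int* b1 = &haps(0, 2 * b);
      const int* b2 = &haps(0, 2 * b + 1);
      scan_pair(a1, b1, chrom, p, cs, ce, minSnps, minLen, rows, a + 1, 1, b + 1, 1);
      scan_pair(a1, b2, chrom, p, cs, ce, minSnps, minLen, rows, a + 1, 1, b + 1, 2);
      scan_pair(a2, b1, chrom, p, cs, ce, minSnps, minLen, rows, a + 1, 2, b + 1, 1);
      scan_pair(a2, b2, chrom, p, cs, ce, minSnps, minLen, rows, a + 1, 2, b + 1, 2);
    }
  }
  const int n = (int)(rows.size() / 8);
  NumericMatrix out(n, 8);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 8; ++k) out(i, k) = rows[8 * i + k];
  colnames(out) = CharacterVector::create("indivA", "hapA", "indivB", "hapB",
                                          "chrom", "startCm", "endCm", "nSnps");
  return out;
}

// ---- interval-based gene drop of a focal founder haplotype ----------------
//
// A lineage of `depth` meioses keeps the focal founder material on a union of
// intervals.  Each meiosis overlays a two-state telegraph process (which
// parental strand the gamete copies; fair-coin start, Poisson(1/Morgan)
// switch points) and intersects the current focal set with the strand that
// carries it.  Gaps between surviving intervals are bridged analytically
// with the Haldane flip probability (1 - exp(-2d/100)) / 2, so the cost is
// proportional to the surviving material, not the chromosome length.

typedef std::vector<std::pair<double, double> > IntervalSet;

static void telegraph_intersect(const IntervalSet& F, double rateCm,
                                IntervalSet& out) {
  out.clear();
  if (F.empty()) return;
  int state = (unif_rand() < 0.5) ? 1 : 0;  // 1 = copying the focal strand
  double at = F[0].first;
  for (size_t i = 0; i < F.size(); ++i) {
    const double s = F[i].first, e = F[i].second;
    if (s > at) {  // bridge the gap analytically
      const double pflip = 0.5 * (1.0 - std::exp(-2.0 * rateCm * (s - at)));
      if (unif_rand() < pflip) state = 1 - state;
    }
    double cur = s;
    while (cur < e) {
      // next switch point within the interval (exponential spacing)
      const double step = R::rexp(1.0) / rateCm;
      const double nxt = cur + step;
      const double stop = std::min(nxt, e);
      if (state == 1 && stop > cur) out.push_back(std::make_pair(cur, stop));
      if (nxt >= e) { cur = e; } else { cur = nxt; state = 1 - state; }
    }
    at = e;
  }
}

static void drop_lineage(double chromLenCm, int depth, IntervalSet& F) {
  const double rate = 0.01;  // crossovers per cM (1 per Morgan)
  F.clear();
  F.push_back(std::make_pair(0.0, chromLenCm));
  IntervalSet nxt;
  for (int d = 0; d < depth; ++d) {
    telegraph_intersect(F, rate, nxt);
    F.swap(nxt);
    if (F.empty()) return;
  }
}

static void intersect_sets(const IntervalSet& A, const IntervalSet& B,
                           std::vector<double>& lengths) {
  size_t i = 0, j = 0;
  while (i < A.size() && j < B.size()) {
    const double lo = std::max(A[i].first, B[j].first);
    const double hi = std::min(A[i].second, B[j].second);
    if (hi > lo) lengths.push_back(hi - lo);
    if (A[i].second < B[j].second) ++i; else ++j;
  }
}

// Lengths (cM) of maximal intervals where two descendants, each `depth`
// meioses below a shared ancestor, both carry the ancestor's focal haplotype.
// [[Rcpp::export]]
NumericVector cpp_shared_ancestral_segments(int nPairs, int depth,
                                            double chromLenCm) {
  std::vector<double> lengths;
  IntervalSet A, B;
  for (int r = 0; r < nPairs; ++r) {
    drop_lineage(chromLenCm, depth, A);
    if (A.empty()) continue;
    drop_lineage(chromLenCm, depth, B);
    if (B.empty()) continue;
    intersect_sets(A, B, lengths);
  }
  return wrap(lengths);
}
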