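#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// Forward diploid Wright-Fisher engine over a 50kb-style locus.
// Population = 2N haplotype rows over the currently segregating columns
// (row-major uint8). Mutations follow the infinite-sites model with
// continuous positions; each column carries a persistent id so that
// haplotypes sampled at ancient generations can be projected onto the
// final (present-day) column set. Uses R's RNG throughout so results are
// reproducible under set.seed().

namespace {

struct Population {
  int nHap = 0;           // 2N
  int nCol = 0;
  std::vector<uint8_t> mat;      // nHap x nCol, row-major
  std::vector<double> pos;       // length nCol, bp
  std::vector<long long> ids;    // length nCol
  long long focalId = -1;        // id of selected column, -1 if none

  int focalCol() const {
    if (focalId < 0) return -1;
    for (int c = 0; c < nCol; ++c) if (ids[c] == focalId) return c;
    return -1;
  }
};

struct SampledBlock {
  int genBP;
  int nHap;
  std::vector<uint8_t> mat;      // nHap x nCol(at sampling time)
  std::vector<long long> ids;
};

inline int pickWeighted(const std::vector<double>& cum, double tot) {
  double u = unif_rand() * tot;
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// Produce one gamete from diploid parent p into dst (stride row of child).
void makeGamete(const Population& pop, int p, uint8_t* dst, double rhoL) {
  const int S = pop.nCol;
  int k = (rhoL > 0) ? (int)R::rpois(rhoL) : 0;
  int start = (unif_rand() < 0.5) ? 0 : 1;
  const uint8_t* h0 = pop.mat.data() + (size_t)(2 * p) * S;
  const uint8_t* h1 = pop.mat.data() + (size_t)(2 * p + 1) * S;
  if (k == 0 || S == 0) {
    const uint8_t* src = start ? h1 : h0;
    std::copy(src, src + S, dst);
    return;
  }
  double bp[8];
  if (k > 8) k = 8;  // >8 crossovers on one gamete is beyond plausible rhoL here
  for (int i = 0; i < k; ++i) bp[i] = unif_rand();
  std::sort(bp, bp + k);
  // pos stored in bp units; breakpoints drawn as fractions of the locus, so
  // compare against pos/L. Caller passes positions as fractions already.
  for (int c = 0; c < S; ++c) {
    int cnt = 0;
    for (int i = 0; i < k; ++i) if (bp[i] < pop.pos[c]) ++cnt;
    int hap = (start + cnt) & 1;
    dst[c] = hap ? h1[c] : h0[c];
  }
}

// One reproduction step: parents pop (size 2N), offspring N2 diploids.
// Selection: genotype fitness 1 : 1+s : 1 at the focal column when present.
void reproduce(const Population& pop, Population& child, int N2,
               double s, double muL, double rhoL, long long& nextId) {
  const int N = pop.nHap / 2;
  const int S = pop.nCol;
  const int fc = pop.focalCol();
  const bool sel = (fc >= 0 && s > 0);

  std::vector<double> cum;
  double tot = 0;
  if (sel) {
    cum.resize(N);
    for (int i = 0; i < N; ++i) {
      int g = pop.mat[(size_t)(2 * i) * S + fc] + pop.mat[(size_t)(2 * i + 1) * S + fc];
      tot += (g == 1) ? 1.0 + s : 1.0;
      cum[i] = tot;
    }
  }

  int nMut = (muL > 0) ? (int)R::rpois(2.0 * N2 * muL) : 0;
  int S2 = S + nMut;
  child.nHap = 2 * N2;
  child.nCol = S2;
  child.mat.assign((size_t)2 * N2 * S2, 0);  // keeps capacity across swaps
  child.pos.resize(S2);
  child.ids.resize(S2);
  std::copy(pop.pos.begin(), pop.pos.end(), child.pos.begin());
  std::copy(pop.ids.begin(), pop.ids.end(), child.ids.begin());
  child.focalId = pop.focalId;

  for (int j = 0; j < N2; ++j) {
    int pa = sel ? pickWeighted(cum, tot) : (int)(unif_rand() * N);
    int pb = sel ? pickWeighted(cum, tot) : (int)(unif_rand() * N);
    if (pa >= N) pa = N - 1;
    if (pb >= N) pb = N - 1;
    makeGamete(pop, pa, child.mat.data() + (size_t)(2 * j) * S2, rhoL);
    makeGamete(pop, pb, child.mat.data() + (size_t)(2 * j + 1) * S2, rhoL);
  }
  for (int m = 0; m < nMut; ++m) {
    int row = (int)(unif_rand() * 2 * N2);
    if (row >= 2 * N2) row = 2 * N2 - 1;
    int c = S + m;
    child.pos[c] = unif_rand();
    child.ids[c] = nextId++;
    child.mat[(size_t)row * S2 + c] = 1;
  }
}

// Drop columns lost or fixed in the population; the focal column is kept.
void prune(Population& pop) {
  const int S = pop.nCol, H = pop.nHap;
  if (S == 0) return;
  std::vector<int> cnt(S, 0);
  const uint8_t* m = pop.mat.data();
  for (int r = 0; r < H; ++r) {
    const uint8_t* row = m + (size_t)r * S;
    for (int c = 0; c < S; ++c) cnt[c] += row[c];
  }
  std::vector<int> keep;
  keep.reserve(S);
  for (int c = 0; c < S; ++c) {
    if ((cnt[c] > 0 && cnt[c] < H) || pop.ids[c] == pop.focalId) keep.push_back(c);
  }
  int S2 = (int)keep.size();
  if (S2 == S) return;
  std::vector<uint8_t> nm((size_t)H * S2);
  for (int r = 0; r < H; ++r) {
    const uint8_t* src = m + (size_t)r * S;
    uint8_t* dst = nm.data() + (size_t)r * S2;
    for (int c = 0; c < S2; ++c) dst[c] = src[keep[c]];
  }
  std::vector<double> np(S2);
  std::vector<long long> ni(S2);
  for (int c = 0; c < S2; ++c) { np[c] = pop.pos[keep[c]]; ni[c] = pop.ids[keep[c]]; }
  pop.mat.swap(nm);
  pop.pos.swap(np);
  pop.ids.swap(ni);
  pop.nCol = S2;
}

void sampleBlock(const Population& pop, int n, int genBP, std::vector<SampledBlock>& out) {
  SampledBlock b;
  b.genBP = genBP;
  b.nHap = n;
  b.ids = pop.ids;
  b.mat.resize((size_t)n * pop.nCol);
  // partial Fisher-Yates without replacement
  std::vector<int> idx(pop.nHap);
  for (int i = 0; i < pop.nHap; ++i) idx[i] = i;
  for (int i = 0; i < n; ++i) {
    int j = i + (int)(unif_rand() * (pop.nHap - i));
    if (j >= pop.nHap) j = pop.nHap - 1;
    std::swap(idx[i], idx[j]);
    std::copy(pop.mat.data() + (size_t)idx[i] * pop.nCol,
              pop.mat.data() + (size_t)(idx[i] + 1) * pop.nCol,
              b.mat.data() + (size_t)i * pop.nCol);
  }
  out.push_back(std::move(b));
}

}  // namespace

// [[Rcpp::export(name = ".wfSimulateCpp")]]
List wfSimulateCpp(IntegerVector popSizeByGenBP,  // [genBP+1] = diploid N; length G
                   double muL, double rhoL,
                   double s, int onsetGen, double focalFrac,
                   IntegerVector sampleGens, IntegerVector sampleSizes,
                   int maxAttempts) {
  const int G = popSizeByGenBP.size();
  const bool selected = onsetGen >= 0;
  const long long NO_FOCAL = -9223372036854775807LL;
  long long nextId = 0;

  // Phase 1: burn-in and any pre-onset history, run once. For selected
  // classes the state at the onset generation is checkpointed; conditioning
  // failures rewind to it (the standard forward-simulation idiom for
  // conditioning on a de novo mutation) and redraw the post-onset phase
  // with fresh random numbers.
  Population pop, child;
  pop.nHap = 2 * popSizeByGenBP[G - 1];
  pop.nCol = 0;
  pop.focalId = NO_FOCAL;
  std::vector<SampledBlock> preBlocks;
  int startGen = selected ? onsetGen : 0;
  for (int genBP = G - 1; genBP > startGen; --genBP) {
    for (int k = 0; k < sampleGens.size(); ++k)
      if (sampleGens[k] == genBP) sampleBlock(pop, sampleSizes[k], genBP, preBlocks);
    reproduce(pop, child, popSizeByGenBP[genBP - 1], 0.0, muL, rhoL, nextId);
    std::swap(pop, child);
    if (genBP % 4 == 1 || genBP <= 1) prune(pop);
  }

  Population checkpoint = pop;  // state at startGen (pre-injection)
  int attempt = 1;
  for (; attempt <= maxAttempts; ++attempt) {
    if (selected) {
      pop = checkpoint;
      // inject de novo focal mutation on one random haplotype
      int row = (int)(unif_rand() * pop.nHap);
      if (row >= pop.nHap) row = pop.nHap - 1;
      int S = pop.nCol, S2 = S + 1;
      std::vector<uint8_t> nm((size_t)pop.nHap * S2, 0);
      for (int r = 0; r < pop.nHap; ++r)
        std::copy(pop.mat.data() + (size_t)r * S, pop.mat.data() + (size_t)(r + 1) * S,
                  nm.data() + (size_t)r * S2);
      nm[(size_t)row * S2 + S] = 1;
      pop.mat.swap(nm);
      pop.pos.push_back(focalFrac);
      long long fid = nextId++;
      pop.ids.push_back(fid);
      pop.focalId = fid;
      pop.nCol = S2;
    }
    std::vector<SampledBlock> postBlocks;
    for (int genBP = startGen; genBP >= 0; --genBP) {
      for (int k = 0; k < sampleGens.size(); ++k)
        if (sampleGens[k] == genBP) sampleBlock(pop, sampleSizes[k], genBP, postBlocks);
      if (genBP > 0) {
        reproduce(pop, child, popSizeByGenBP[genBP - 1], s, muL, rhoL, nextId);
        std::swap(pop, child);
        if (genBP % 4 == 1 || genBP <= 1) prune(pop);
      }
    }

    if (selected) {
      int fc = pop.focalCol();
      int cnt = 0;
      if (fc >= 0)
        for (int r = 0; r < pop.nHap; ++r) cnt += pop.mat[(size_t)r * pop.nCol + fc];
      if (fc < 0 || cnt == 0 || cnt == pop.nHap) continue;  // retry from checkpoint
    }

    // assemble: final column set = present-day population columns
    std::vector<SampledBlock> blocks = preBlocks;
    for (auto& b : postBlocks) blocks.push_back(std::move(b));
    const int Sf = pop.nCol;
    std::unordered_map<long long, int> colOf;
    colOf.reserve(Sf * 2);
    for (int c = 0; c < Sf; ++c) colOf[pop.ids[c]] = c;
    List outBlocks(blocks.size());
    IntegerVector ages(blocks.size());
    for (size_t b = 0; b < blocks.size(); ++b) {
      const SampledBlock& bl = blocks[b];
      IntegerMatrix M(bl.nHap, Sf);
      int Sb = (int)bl.ids.size();
      std::vector<int> map(Sb, -1);
      for (int c = 0; c < Sb; ++c) {
        auto it = colOf.find(bl.ids[c]);
        if (it != colOf.end()) map[c] = it->second;
      }
      for (int r = 0; r < bl.nHap; ++r)
        for (int c = 0; c < Sb; ++c)
          if (map[c] >= 0) M(r, map[c]) = bl.mat[(size_t)r * Sb + c];
      outBlocks[b] = M;
      ages[b] = bl.genBP;
    }
    return List::create(
        _["blocks"] = outBlocks, _["blockGens"] = ages,
        _["positions"] = NumericVector(pop.pos.begin(), pop.pos.end()),
        _["focalIndex"] = pop.focalCol() + 1,  // 1-based; 0 if absent
        _["attempts"] = attempt, _["success"] = true);
  }
  return List::create(_["success"] = false, _["attempts"] = maxAttempts);
}

// Single Wright-Fisher generation on an explicit population state; shares the
// reproduction code with the full engine. Haplotype matrix is nHap x S (0/1),
// positions are fractions of the locus.
// [[Rcpp::export(name = ".wfEvolveOnceCpp")]]
List wfEvolveOnceCpp(IntegerMatrix hap, NumericVector posFrac, int focalCol1,
                     int nextN, double s, double muL, double rhoL) {
  Population pop, child;
  pop.nHap = hap.nrow();
  pop.nCol = hap.ncol();
  pop.mat.resize((size_t)pop.nHap * pop.nCol);
  for (int r = 0; r < pop.nHap; ++r)
    for (int c = 0; c < pop.nCol; ++c)
      pop.mat[(size_t)r * pop.nCol + c] = (uint8_t)hap(r, c);
  pop.pos.assign(posFrac.begin(), posFrac.end());
  pop.ids.resize(pop.nCol);
  for (int c = 0; c < pop.nCol; ++c) pop.ids[c] = c;
  pop.focalId = (focalCol1 >= 1) ? (long long)(focalCol1 - 1) : -9223372036854775807LL;

  long long nextId = pop.nCol;
  reproduce(pop, child, nextN, s, muL, rhoL, nextId);

  IntegerMatrix M(child.nHap, child.nCol);
  for (int r = 0; r < child.nHap; ++r)
    for (int c = 0; c < child.nCol; ++c)
      M(r, c) = child.mat[(size_t)r * child.nCol + c];
  int fc = child.focalCol();
  return List::create(_["haplotypes"] = M,
                      _["positions"] = NumericVector(child.pos.begin(), child.pos.end()),
                      _["focalIndex"] = fc + 1);
}
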