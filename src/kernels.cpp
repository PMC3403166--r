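#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <unordered_map>
#include <vector>
#include <limits>
#include <string>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return 4;  // any ambiguity code: background emission / mismatch
  }
}

static inline char complementBase(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'C': return 'G'; case 'G': return 'C';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    default:  return 'N';
  }
}

static std::string revComp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = complementBase(s[i]);
  return out;
}

// transition column order (0-based) in the (M-1) x 9 matrix:
// 0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 ID, 6 DM, 7 DI, 8 DD
enum { TMM = 0, TMI, TMD, TIM, TII, TID, TDM, TDI, TDD };

struct ViterbiResult {
  double score;
  int readStart, readEnd;    // 0-based half-open, on the scanned strand
  int modelStart, modelEnd;  // 1-based match-state indices, inclusive
  std::vector<int> pType, pModel, pRead;  // traceback path
  bool found;
};

// Local profile-HMM Viterbi: free entry into any match state at any read
// position, free exit after any match state, zero-cost flanking residues.
// Emissions are log2-odds vs uniform background; non-ACGT residues emit 0.
// Tie-break among predecessors: M over D over I over fresh entry.
static ViterbiResult viterbiLocal(const NumericMatrix& matchEm,
                                  const NumericMatrix& insertEm,
                                  const NumericMatrix& trans,
                                  const std::string& seq,
                                  bool wantPath) {
  const int M = matchEm.nrow();
  const int L = (int) seq.size();
  ViterbiResult res;
  res.found = false;
  res.score = NEG_INF;
  if (L == 0 || M == 0) return res;

  std::vector<int> code(L);
  for (int i = 0; i < L; ++i) code[i] = baseCode(seq[i]);

  const int W = M + 1;
  std::vector<double> VM((L + 1) * W, NEG_INF), VI((L + 1) * W, NEG_INF),
      VD((L + 1) * W, NEG_INF);
  // predecessor codes: 0 entry, 1 M, 2 I, 3 D
  std::vector<unsigned char> BM((L + 1) * W, 0), BI((L + 1) * W, 0),
      BD((L + 1) * W, 0);

  auto at = [W](int i, int j) { return i * W + j; };

  double best = NEG_INF;
  int bi = -1, bj = -1;

  for (int i = 1; i <= L; ++i) {
    const int b = code[i - 1];
    for (int j = 1; j <= M; ++j) {
      // match state j consuming residue i
      double em = (b < 4) ? matchEm(j - 1, b) : 0.0;
      double bestPred = 0.0;             // fresh entry (checked last for ties)
      unsigned char who = 0;
      if (j >= 2 && i >= 2) {
        double vm = VM[at(i - 1, j - 1)] + trans(j - 2, TMM);
        double vd = VD[at(i - 1, j - 1)] + trans(j - 2, TDM);
        double vi = VI[at(i - 1, j - 1)] + trans(j - 2, TIM);
        // preference M > D > I > entry on exact ties
        double bp = vm; unsigned char w = 1;
        if (vd > bp) { bp = vd; w = 3; }
        if (vi > bp) { bp = vi; w = 2; }
        if (bp >= 0.0) { bestPred = bp; who = w; }  // continuation beats entry on ties
      }
      double v = em + bestPred;
      VM[at(i, j)] = v;
      BM[at(i, j)] = who;
      if (v > best) { best = v; bi = i; bj = j; }

      // insert state j (between match j and j+1), j = 1..M-1
      if (j <= M - 1 && i >= 2) {
        double emI = (b < 4) ? insertEm(j - 1, b) : 0.0;
        double vm = VM[at(i - 1, j)] + trans(j - 1, TMI);
        double vd = VD[at(i - 1, j)] + trans(j - 1, TDI);
        double vi = VI[at(i - 1, j)] + trans(j - 1, TII);
        double bp = vm; unsigned char w = 1;
        if (vd > bp) { bp = vd; w = 3; }
        if (vi > bp) { bp = vi; w = 2; }
        if (bp > NEG_INF) {
          VI[at(i, j)] = emI + bp;
          BI[at(i, j)] = w;
        }
      }

      // delete state j (no residue consumed), j = 2..M; fed from column j-1
      if (j >= 2) {
        double vm = VM[at(i, j - 1)] + trans(j - 2, TMD);
        double vd = VD[at(i, j - 1)] + trans(j - 2, TDD);
        double vi = (j - 1 <= M - 1) ? VI[at(i, j - 1)] + trans(j - 2, TID)
                                     : NEG_INF;
        double bp = vm; unsigned char w = 1;
        if (vd > bp) { bp = vd; w = 3; }
        if (vi > bp) { bp = vi; w = 2; }
        if (bp > NEG_INF) {
          VD[at(i, j)] = bp;
          BD[at(i, j)] = w;
        }
      }
    }
  }

  if (bi < 0) return res;
  res.found = true;
  res.score = best;

  // traceback from (bi, bj) in state M
  int i = bi, j = bj, type = 1;  // 1 = M, 2 = I, 3 = D
  std::vector<int> pt, pj, pi;
  while (true) {
    pt.push_back(type); pj.push_back(j); pi.push_back(type == 3 ? NA_INTEGER : i);
    unsigned char who;
    if (type == 1) who = BM[at(i, j)];
    else if (type == 2) who = BI[at(i, j)];
    else who = BD[at(i, j)];
    if (type == 1) {
      if (who == 0) break;             // entry point
      --i; --j; type = who;
    } else if (type == 2) {
      --i; type = who;
    } else {                            // delete: consumed no residue
      --j; type = who;
    }
  }
  std::reverse(pt.begin(), pt.end());
  std::reverse(pj.begin(), pj.end());
  std::reverse(pi.begin(), pi.end());

  res.modelStart = pj.front();
  res.modelEnd = pj.back();
  // first and last states are match states (entry/exit only at M)
  int firstRead = L + 1, lastRead = 0;
  for (size_t k = 0; k < pi.size(); ++k) {
    if (pt[k] != 3) {
      if (pi[k] < firstRead) firstRead = pi[k];
      if (pi[k] > lastRead) lastRead = pi[k];
    }
  }
  res.readStart = firstRead - 1;  // 0-based half-open
  res.readEnd = lastRead;
  if (wantPath) { res.pType = pt; res.pModel = pj; res.pRead = pi; }
  return res;
}

// [[Rcpp::export]]
List viterbi_cpp(NumericMatrix matchEm, NumericMatrix insertEm,
                 NumericMatrix trans, std::string seq) {
  ViterbiResult r = viterbiLocal(matchEm, insertEm, trans, seq, true);
  if (!r.found) return List::create(Named("score") = R_NegInf);
  IntegerMatrix path(r.pType.size(), 3);
  for (size_t k = 0; k < r.pType.size(); ++k) {
    path(k, 0) = r.pType[k];
    path(k, 1) = r.pModel[k];
    path(k, 2) = r.pRead[k];
  }
  colnames(path) = CharacterVector::create("state", "model", "read");
  return List::create(
      Named("score") = r.score, Named("path") = path,
      Named("readStart") = r.readStart, Named("readEnd") = r.readEnd,
      Named("modelStart") = r.modelStart, Named("modelEnd") = r.modelEnd);
}

// Scan a batch of reads on both strands, keep the better strand per read,
// report hits meeting minScore. Intervals are on the reported strand.
// [[Rcpp::export]]
DataFrame scan_reads_cpp(CharacterVector reads, NumericMatrix matchEm,
                         NumericMatrix insertEm, NumericMatrix trans,
                         double minScore) {
  std::vector<int> ord;
  std::vector<std::string> strand;
  std::vector<int> rs, re, ms, me;
  std::vector<double> sc;
  for (int k = 0; k < reads.size(); ++k) {
    std::string fwd = as<std::string>(reads[k]);
    std::string rev = revComp(fwd);
    ViterbiResult rf = viterbiLocal(matchEm, insertEm, trans, fwd, false);
    ViterbiResult rr = viterbiLocal(matchEm, insertEm, trans, rev, false);
    bool plus = true;
    if (rr.found && (!rf.found || rr.score > rf.score)) plus = false;
    const ViterbiResult& rbest = plus ? rf : rr;
    if (!rbest.found || rbest.score < minScore) continue;
    ord.push_back(k + 1);
    strand.push_back(plus ? "+" : "-");
    rs.push_back(rbest.readStart);
    re.push_back(rbest.readEnd);
    ms.push_back(rbest.modelStart);
    me.push_back(rbest.modelEnd);
    sc.push_back(rbest.score);
  }
  return DataFrame::create(
      Named("ord") = ord, Named("strand") = strand, Named("readStart") = rs,
      Named("readEnd") = re, Named("modelStart") = ms, Named("modelEnd") = me,
      Named("score") = sc, Named("stringsAsFactors") = false);
}

// ---------------------------------------------------------------------------
// Seed-and-extend aligner
// ---------------------------------------------------------------------------

struct Ungapped { long score; int q0, q1, diag; bool found; };

// best ungapped segment on one diagonal, seeded by the merged w-mer extent,
// extended both ways with X-drop termination
static Ungapped extendDiag(const std::string& q, const std::string& r,
                           int diag, int seedQ0, int seedQ1,
                           int matchS, int mismatchS, int xdrop) {
  Ungapped u; u.diag = diag; u.found = true;
  long mid = 0;
  for (int qi = seedQ0; qi < seedQ1; ++qi) {
    char a = q[qi], b = r[qi - diag];
    mid += (a == b && baseCode(a) < 4) ? matchS : mismatchS;
  }
  // right extension
  long cur = 0, bestGain = 0; int q1 = seedQ1;
  for (int qi = seedQ1; qi < (int) q.size() && qi - diag < (int) r.size(); ++qi) {
    char a = q[qi], b = r[qi - diag];
    cur += (a == b && baseCode(a) < 4) ? matchS : mismatchS;
    if (cur > bestGain) { bestGain = cur; q1 = qi + 1; }
    if (bestGain - cur > xdrop) break;
  }
  long right = bestGain;
  // left extension
  cur = 0; bestGain = 0; int q0 = seedQ0;
  for (int qi = seedQ0 - 1; qi >= 0 && qi - diag >= 0; --qi) {
    char a = q[qi], b = r[qi - diag];
    cur += (a == b && baseCode(a) < 4) ? matchS : mismatchS;
    if (cur > bestGain) { bestGain = cur; q0 = qi; }
    if (bestGain - cur > xdrop) break;
  }
  u.score = mid + right + bestGain;
  u.q0 = q0; u.q1 = q1;
  return u;
}

struct BandedHit {
  long score;
  int qs, qe, ss, se;        // 0-based half-open
  int length, mismatches, gapOpens, matches;
  bool found;
};

// banded affine local alignment restricted to diagonals diag0 +/- band,
// with full traceback for identity / mismatch / gap statistics
static BandedHit bandedLocal(const std::string& q, const std::string& r,
                             int diag0, int band, int matchS, int mismatchS,
                             int gapOpen, int gapExtend) {
  const int m = (int) q.size(), n = (int) r.size();
  const int W = 2 * band + 1;
  BandedHit out; out.found = false; out.score = 0;

  std::vector<long> H(m * W, 0), E(m * W, LONG_MIN / 4), F(m * W, LONG_MIN / 4);
  // tb: bits 0-1 H source (0 stop, 1 diag, 2 E, 3 F); bit 2 E opened; bit 3 F opened
  std::vector<unsigned char> tb(m * W, 0);

  long best = 0; int bi = -1, bk = -1;
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i - diag0 + (k - band);  // ref position
      if (j < 0 || j >= n) continue;
      // E: gap in query (consumes ref), from (i, j-1) = (i, k-1)
      long e = LONG_MIN / 4; bool eOpen = false;
      if (k - 1 >= 0) {
        int jp = j - 1;
        if (jp >= 0) {
          long fromH = H[i * W + (k - 1)] + gapOpen + gapExtend;
          long fromE = E[i * W + (k - 1)] + gapExtend;
          if (fromH >= fromE) { e = fromH; eOpen = true; }
          else e = fromE;
        }
      }
      // F: gap in ref (consumes query), from (i-1, j) = (i-1, k+1)
      long f = LONG_MIN / 4; bool fOpen = false;
      if (i - 1 >= 0 && k + 1 < W) {
        long fromH = H[(i - 1) * W + (k + 1)] + gapOpen + gapExtend;
        long fromF = F[(i - 1) * W + (k + 1)] + gapExtend;
        if (fromH >= fromF) { f = fromH; fOpen = true; }
        else f = fromF;
      }
      // H
      long diagH = 0;
      if (i - 1 >= 0 && j - 1 >= 0) diagH = H[(i - 1) * W + k];
      char a = q[i], b = r[j];
      long sub = (a == b && baseCode(a) < 4) ? matchS : mismatchS;
      long hDiag = diagH + sub;  // includes starting fresh (diagH may be 0 cell)
      long h = 0; unsigned char src = 0;
      if (hDiag > h) { h = hDiag; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      int idx = i * W + k;
      H[idx] = h; E[idx] = e; F[idx] = f;
      tb[idx] = src | (eOpen ? 4 : 0) | (fOpen ? 8 : 0);
      if (h > best) { best = h; bi = i; bk = k; }
    }
  }
  if (bi < 0 || best <= 0) return out;

  // traceback
  int i = bi, k = bk;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  int matches = 0, mismatches = 0, gapOpens = 0, cols = 0;
  int qe = bi + 1, se = bi - diag0 + (bk - band) + 1;
  int qs = bi, ss = se - 1;
  while (i >= 0 && k >= 0 && k < W) {
    int j = i - diag0 + (k - band);
    if (j < 0) break;
    int idx = i * W + k;
    if (state == 0) {
      unsigned char src = tb[idx] & 3;
      if (src == 0) break;
      if (src == 1) {
        char a = q[i], b = r[j];
        if (a == b && baseCode(a) < 4) ++matches; else ++mismatches;
        ++cols; qs = i; ss = j;
        --i;  // k unchanged: (i-1, j-1)
        if (i < 0 || j - 1 < 0) break;   // reached matrix edge: local start
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // gap in query consuming ref base j
      ++cols; ss = j;
      bool opened = (tb[idx] & 4) != 0;
      if (opened) { ++gapOpens; state = 0; }
      --k;  // (i, j-1)
    } else {
      // gap in ref consuming query base i
      ++cols; qs = i;
      bool opened = (tb[idx] & 8) != 0;
      if (opened) { ++gapOpens; state = 0; }
      --i; ++k;  // (i-1, j)
    }
  }

  out.found = true;
  out.score = best;
  out.qs = qs; out.qe = qe; out.ss = ss; out.se = se;
  out.length = cols; out.matches = matches; out.mismatches = mismatches;
  out.gapOpens = gapOpens;
  return out;
}

// [[Rcpp::export]]
DataFrame align_batch_cpp(CharacterVector queries, CharacterVector refs,
                          int w, int matchS, int mismatchS, int gapOpen,
                          int gapExtend, int xdrop, int band) {
  const int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int t = 0; t < nref; ++t) R[t] = as<std::string>(refs[t]);

  // index reference w-mers (2-bit encoded); k-mers containing non-ACGT skipped
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  const uint64_t mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  for (int t = 0; t < nref; ++t) {
    const std::string& s = R[t];
    uint64_t kmer = 0; int run = 0;
    for (int p = 0; p < (int) s.size(); ++p) {
      int c = baseCode(s[p]);
      if (c >= 4) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t) c) & mask;
      if (++run >= w) index[kmer].push_back(std::make_pair(t, p - w + 1));
    }
  }

  std::vector<int> outQ, outR, outQs, outQe, outSs, outSe;
  std::vector<int> outLen, outMis, outGap, outMatch;
  std::vector<long> outScore;
  std::vector<std::string> outStrand;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    for (int sidx = 0; sidx < 2; ++sidx) {
      std::string qs = (sidx == 0) ? fwd : revComp(fwd);
      if ((int) qs.size() < w) continue;
      // seeds: per ref, per diagonal, merged q extent
      std::map<int, std::map<int, std::pair<int, int>>> seeds;
      uint64_t kmer = 0; int run = 0;
      for (int p = 0; p < (int) qs.size(); ++p) {
        int c = baseCode(qs[p]);
        if (c >= 4) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t) c) & mask;
        if (++run >= w) {
          auto it = index.find(kmer);
          if (it == index.end()) continue;
          int q0 = p - w + 1;
          for (size_t h = 0; h < it->second.size(); ++h) {
            int t = it->second[h].first, rp = it->second[h].second;
            int diag = q0 - rp;
            auto& dmap = seeds[t];
            auto dit = dmap.find(diag);
            if (dit == dmap.end()) dmap[diag] = std::make_pair(q0, q0);
            else {
              if (q0 < dit->second.first) dit->second.first = q0;
              if (q0 > dit->second.second) dit->second.second = q0;
            }
          }
        }
      }
      for (auto rit = seeds.begin(); rit != seeds.end(); ++rit) {
        int t = rit->first;
        Ungapped bestU; bestU.found = false; bestU.score = LONG_MIN;
        for (auto dit = rit->second.begin(); dit != rit->second.end(); ++dit) {
          Ungapped u = extendDiag(qs, R[t], dit->first, dit->second.first,
                                  dit->second.second + w, matchS, mismatchS,
                                  xdrop);
          if (!bestU.found || u.score > bestU.score) bestU = u;
        }
        if (!bestU.found || bestU.score <= 0) continue;
        BandedHit b = bandedLocal(qs, R[t], bestU.diag, band, matchS,
                                  mismatchS, gapOpen, gapExtend);
        if (!b.found || b.score <= 0) continue;
        outQ.push_back(qi + 1);
        outR.push_back(t + 1);
        outStrand.push_back(sidx == 0 ? "+" : "-");
        outScore.push_back(b.score);
        outQs.push_back(b.qs); outQe.push_back(b.qe);
        outSs.push_back(b.ss); outSe.push_back(b.se);
        outLen.push_back(b.length); outMis.push_back(b.mismatches);
        outGap.push_back(b.gapOpens); outMatch.push_back(b.matches);
      }
    }
  }

  return DataFrame::create(
      Named("query") = outQ, Named("ref") = outR, Named("strand") = outStrand,
      Named("score") = outScore, Named("qs") = outQs, Named("qe") = outQe,
      Named("ss") = outSs, Named("se") = outSe, Named("length") = outLen,
      Named("mismatch") = outMis, Named("gapopen") = outGap,
      Named("matches") = outMatch, Named("stringsAsFactors") = false);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revComp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
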