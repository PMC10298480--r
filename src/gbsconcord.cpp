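#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---- ungapped identity helpers -------------------------------------------

// Matches between a and b when b starts at offset `off` relative to a
// (off may be negative). Early abort once more than max_mm mismatches seen
// inside the overlap. Returns matches, or -1 if aborted.
static int overlap_matches(const char *a, int la, const char *b, int lb,
                           int off, int max_mm) {
  int start_a = off > 0 ? off : 0;
  int start_b = off > 0 ? 0 : -off;
  int n = std::min(la - start_a, lb - start_b);
  if (n <= 0) return 0;
  int mm = 0, match = 0;
  for (int i = 0; i < n; ++i) {
    if (a[start_a + i] == b[start_b + i]) ++match;
    else if (++mm > max_mm) return -1;
  }
  return match;
}

// Best identity = matches / min(la, lb) over all offsets with enough overlap.
static double best_pair_identity(const char *a, int la, const char *b, int lb,
                                 double threshold) {
  int den = std::min(la, lb);
  int need = (int)std::ceil(threshold * den);
  double best = 0.0;
  for (int off = -(lb - need); off <= la - need; ++off) {
    int m = overlap_matches(a, la, b, lb, off, den - need);
    if (m > best) best = m;
  }
  return best / den;
}

// ---- bulk single-character edits -----------------------------------------

// Replace character at 1-based position pos[e] of seqs[idx[e]] with base[e].
// Used by the read simulator for heterozygous allele flips, sequencing-error
// injection, and quality-string adjustment.
// [[Rcpp::export]]
CharacterVector cpp_apply_edits(CharacterVector seqs, IntegerVector idx,
                                IntegerVector pos, CharacterVector base) {
  CharacterVector out = clone(seqs);
  int ne = idx.size();
  for (int e = 0; e < ne; ++e) {
    int i = idx[e] - 1;
    std::string s = as<std::string>(out[i]);
    int p = pos[e] - 1;
    if (p < 0 || p >= (int)s.size()) stop("edit position out of range");
    s[p] = CHAR(STRING_ELT(base, e))[0];
    out[i] = s;
  }
  return out;
}

// ---- barcode assignment ---------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_assign_barcodes(CharacterVector reads, CharacterVector barcodes,
                                  int max_mm) {
  int nr = reads.size(), nb = barcodes.size();
  std::vector<std::string> bc(nb);
  for (int j = 0; j < nb; ++j) bc[j] = as<std::string>(barcodes[j]);
  IntegerVector out(nr);
  // exact path: hash on each distinct barcode length
  if (max_mm == 0) {
    std::unordered_map<std::string, int> idx;
    std::vector<int> lens;
    for (int j = 0; j < nb; ++j) {
      idx[bc[j]] = j + 1;
      if (std::find(lens.begin(), lens.end(), (int)bc[j].size()) == lens.end())
        lens.push_back(bc[j].size());
    }
    for (int i = 0; i < nr; ++i) {
      const char *r = CHAR(STRING_ELT(reads, i));
      int lr = LENGTH(STRING_ELT(reads, i));
      int hit = 0;
      for (int l : lens) {
        if (lr < l) continue;
        auto it = idx.find(std::string(r, l));
        if (it != idx.end()) { hit = it->second; break; }
      }
      out[i] = hit;
    }
    return out;
  }
  for (int i = 0; i < nr; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int lr = LENGTH(STRING_ELT(reads, i));
    int hit = 0;
    for (int j = 0; j < nb; ++j) {
      int lb = bc[j].size();
      if (lr < lb) continue;
      int mm = 0;
      for (int p = 0; p < lb && mm <= max_mm; ++p)
        if (r[p] != bc[j][p]) ++mm;
      if (mm <= max_mm) { hit = j + 1; break; }
    }
    out[i] = hit;
  }
  return out;
}

// ---- contaminant screen ---------------------------------------------------

static inline bool encode_kmer(const char *s, int k, uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break; case 'C': v = 1; break;
      case 'G': v = 2; break; case 'T': v = 3; break;
      default: return false;
    }
    code = (code << 2) | v;
  }
  return true;
}

// TRUE where the read's best ungapped full-length alignment inside any
// contaminant reaches min_identity. Seeded with 11-mers so clean reads are
// cheap to clear.
// [[Rcpp::export]]
LogicalVector cpp_screen_reads(CharacterVector reads, CharacterVector contams,
                               double min_identity) {
  const int K = 11;
  int nr = reads.size(), nc = contams.size();
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  std::vector<std::string> cs(nc);
  for (int c = 0; c < nc; ++c) {
    cs[c] = as<std::string>(contams[c]);
    for (int p = 0; p + K <= (int)cs[c].size(); ++p) {
      uint64_t code;
      if (encode_kmer(cs[c].c_str() + p, K, code))
        index[code].push_back({c, p});
    }
  }
  LogicalVector out(nr);
  for (int i = 0; i < nr; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int lr = LENGTH(STRING_ELT(reads, i));
    if (lr < K) { out[i] = false; continue; }
    int max_mm = lr - (int)std::ceil(min_identity * lr);
    bool hit = false;
    std::vector<std::pair<int,int>> seen;  // (contig, offset) already tried
    for (int p = 0; p + K <= lr && !hit; p += 2) {
      uint64_t code;
      if (!encode_kmer(r + p, K, code)) continue;
      auto it = index.find(code);
      if (it == index.end()) continue;
      for (auto &cp : it->second) {
        int off = cp.second - p;  // read start within contaminant
        if (off < 0 || off + lr > (int)cs[cp.first].size()) continue;
        std::pair<int,int> key(cp.first, off);
        if (std::find(seen.begin(), seen.end(), key) != seen.end()) continue;
        seen.push_back(key);
        int m = overlap_matches(cs[cp.first].c_str(), cs[cp.first].size(),
                                r, lr, off, max_mm);
        if (m >= 0 && m >= lr - max_mm) { hit = true; break; }
      }
    }
    out[i] = hit;
  }
  return out;
}

// ---- greedy incremental clustering ---------------------------------------

// Sequences must arrive pre-sorted (abundance desc, length desc, lexicographic).
// Each sequence joins the FIRST representative with identity >= threshold,
// else founds a new cluster. Returns 1-based index of each sequence's
// representative (within the input ordering).
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold) {
  int n = seqs.size();
  IntegerVector rep(n);
  std::vector<int> reps;
  reps.reserve(n);
  for (int i = 0; i < n; ++i) {
    const char *si = CHAR(STRING_ELT(seqs, i));
    int li = LENGTH(STRING_ELT(seqs, i));
    int found = 0;
    for (int r : reps) {
      const char *sr = CHAR(STRING_ELT(seqs, r));
      int lr = LENGTH(STRING_ELT(seqs, r));
      if (best_pair_identity(sr, lr, si, li, threshold) >= threshold) {
        found = r + 1;
        break;
      }
    }
    if (!found) { reps.push_back(i); found = i + 1; }
    rep[i] = found;
  }
  return rep;
}

// ---- read mapping ---------------------------------------------------------

// Best-identity ungapped placement of each read on the contig set, seeded with
// 16-mers. Identity = matches / read length. Ties between distinct contigs at
// the top identity leave the read unmapped. Mapping quality is an
// ambiguity-based surrogate: posterior error under a symmetric mismatch model
// across the seeded candidate contigs, -10*log10, capped at 60.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                   double min_identity, double map_eps) {
  const int K = 16, STEP = 5;
  int nr = reads.size(), nc = contigs.size();
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  std::vector<std::string> cseq(nc);
  for (int c = 0; c < nc; ++c) {
    cseq[c] = as<std::string>(contigs[c]);
    for (int p = 0; p + K <= (int)cseq[c].size(); ++p) {
      uint64_t code;
      if (encode_kmer(cseq[c].c_str() + p, K, code))
        index[code].push_back({c, p});
    }
  }
  IntegerVector contig_out(nr), offset_out(nr), mism_out(nr), mapq_out(nr);
  double lp_mm = std::log(map_eps / 3.0), lp_m = std::log(1.0 - map_eps);
  for (int i = 0; i < nr; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int lr = LENGTH(STRING_ELT(reads, i));
    // candidate (contig, offset) pairs from seeds
    std::vector<int> seed_pos;
    for (int p = 0; p + K <= lr; p += STEP) seed_pos.push_back(p);
    if (lr >= K && (seed_pos.empty() || seed_pos.back() != lr - K))
      seed_pos.push_back(lr - K);
    std::vector<std::pair<int,int>> cand;
    for (int p : seed_pos) {
      uint64_t code;
      if (!encode_kmer(r + p, K, code)) continue;
      auto it = index.find(code);
      if (it == index.end()) continue;
      for (auto &cp : it->second) {
        std::pair<int,int> key(cp.first, cp.second - p);
        if (std::find(cand.begin(), cand.end(), key) == cand.end())
          cand.push_back(key);
      }
    }
    // best placement per contig
    std::unordered_map<int, std::pair<int,int>> per_contig;  // contig -> (matches, offset)
    for (auto &co : cand) {
      int m = overlap_matches(cseq[co.first].c_str(), cseq[co.first].size(),
                              r, lr, co.second, lr);
      if (m < 0) continue;
      auto it = per_contig.find(co.first);
      if (it == per_contig.end() || m > it->second.first)
        per_contig[co.first] = {m, co.second};
    }
    int best_c = -1, best_m = -1, best_off = 0, second_m = -1;
    for (auto &pc : per_contig) {
      if (pc.second.first > best_m) {
        second_m = best_m;
        best_m = pc.second.first; best_c = pc.first; best_off = pc.second.second;
      } else if (pc.second.first > second_m) second_m = pc.second.first;
    }
    double ident = best_m < 0 ? 0.0 : (double)best_m / lr;
    if (best_c < 0 || ident < min_identity || (second_m == best_m && second_m >= 0)) {
      contig_out[i] = 0;
      continue;
    }
    // posterior error over seeded candidates
    double denom = 0.0, lbest = best_m * lp_m + (lr - best_m) * lp_mm;
    for (auto &pc : per_contig) {
      int m = pc.second.first;
      denom += std::exp(m * lp_m + (lr - m) * lp_mm - lbest);
    }
    double err = std::max(1.0 - 1.0 / denom, 1e-6);
    int mq = (int)std::lround(-10.0 * std::log10(err));
    if (mq > 60) mq = 60;
    contig_out[i] = best_c + 1;
    offset_out[i] = best_off;
    mism_out[i] = lr - best_m;
    mapq_out[i] = mq;
  }
  return List::create(_["contig"] = contig_out, _["offset"] = offset_out,
                      _["mismatches"] = mism_out, _["mapq"] = mapq_out);
}

// ---- pileup and candidate site extraction --------------------------------

// [[Rcpp::export]]
List cpp_pileup_sites(CharacterVector reads, CharacterVector quals,
                      IntegerVector ind, IntegerVector contig,
                      IntegerVector offset, IntegerVector mapq,
                      CharacterVector contig_seqs, int n_ind,
                      int min_allele_count) {
  int nr = reads.size(), nc = contig_seqs.size();
  std::vector<int> clen(nc), cstart(nc + 1, 0);
  for (int c = 0; c < nc; ++c) {
    clen[c] = LENGTH(STRING_ELT(contig_seqs, c));
    cstart[c + 1] = cstart[c] + clen[c];
  }
  int tot = cstart[nc];
  std::vector<int> counts(tot * 4, 0);
  std::vector<double> mq2(tot, 0.0);
  std::vector<int> cov(tot, 0);
  auto base_idx = [](char b) -> int {
    switch (b) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  for (int i = 0; i < nr; ++i) {
    int c = contig[i];
    if (c == 0) continue;
    --c;
    const char *r = CHAR(STRING_ELT(reads, i));
    int lr = LENGTH(STRING_ELT(reads, i));
    for (int j = 0; j < lr; ++j) {
      int p = offset[i] + j;
      if (p < 0 || p >= clen[c]) continue;
      int b = base_idx(r[j]);
      if (b < 0) continue;
      int cell = cstart[c] + p;
      ++counts[cell * 4 + b];
      mq2[cell] += (double)mapq[i] * mapq[i];
      ++cov[cell];
    }
  }
  // candidate sites: >=2 alleles with count >= min_allele_count
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::vector<int> site_of(tot, -1);
  std::vector<int> s_contig, s_pos, s_nallele;
  std::vector<char> s_ref, s_alt;
  std::vector<double> s_mq;
  for (int c = 0; c < nc; ++c) {
    for (int p = 0; p < clen[c]; ++p) {
      int cell = cstart[c] + p;
      int n_ge = 0;
      for (int b = 0; b < 4; ++b)
        if (counts[cell * 4 + b] >= min_allele_count) ++n_ge;
      if (n_ge < 2) continue;
      // ref = most frequent (lexicographic tie-break), alt = runner-up
      int ref = 0, alt = -1;
      for (int b = 1; b < 4; ++b)
        if (counts[cell * 4 + b] > counts[cell * 4 + ref]) ref = b;
      for (int b = 0; b < 4; ++b) {
        if (b == ref) continue;
        if (alt < 0 || counts[cell * 4 + b] > counts[cell * 4 + alt]) alt = b;
      }
      site_of[cell] = s_contig.size();
      s_contig.push_back(c + 1);
      s_pos.push_back(p);
      s_ref.push_back(BASES[ref]);
      s_alt.push_back(BASES[alt]);
      s_nallele.push_back(n_ge);
      s_mq.push_back(std::sqrt(mq2[cell] / cov[cell]));
    }
  }
  int ns = s_contig.size();
  IntegerMatrix ref_depth(n_ind, ns), alt_depth(n_ind, ns);
  std::vector<std::vector<int>> bq_ref(ns), bq_alt(ns), mq_ref(ns), mq_alt(ns);
  for (int i = 0; i < nr; ++i) {
    int c = contig[i];
    if (c == 0) continue;
    --c;
    const char *r = CHAR(STRING_ELT(reads, i));
    const char *q = CHAR(STRING_ELT(quals, i));
    int lr = LENGTH(STRING_ELT(reads, i));
    int who = ind[i] - 1;
    for (int j = 0; j < lr; ++j) {
      int p = offset[i] + j;
      if (p < 0 || p >= clen[c]) continue;
      int s = site_of[cstart[c] + p];
      if (s < 0) continue;
      int bq = (int)q[j] - 33;
      if (r[j] == s_ref[s]) {
        ++ref_depth(who, s);
        bq_ref[s].push_back(bq);
        mq_ref[s].push_back(mapq[i]);
      } else if (r[j] == s_alt[s]) {
        ++alt_depth(who, s);
        bq_alt[s].push_back(bq);
        mq_alt[s].push_back(mapq[i]);
      }
    }
  }
  List lbr(ns), lba(ns), lmr(ns), lma(ns);
  CharacterVector refv(ns), altv(ns);
  for (int s = 0; s < ns; ++s) {
    lbr[s] = wrap(bq_ref[s]); lba[s] = wrap(bq_alt[s]);
    lmr[s] = wrap(mq_ref[s]); lma[s] = wrap(mq_alt[s]);
    refv[s] = std::string(1, s_ref[s]);
    altv[s] = std::string(1, s_alt[s]);
  }
  return List::create(
    _["contig"] = wrap(s_contig), _["pos0"] = wrap(s_pos),
    _["ref"] = refv, _["alt"] = altv, _["n_alleles"] = wrap(s_nallele),
    _["mq"] = wrap(s_mq), _["ref_depth"] = ref_depth, _["alt_depth"] = alt_depth,
    _["bq_ref"] = lbr, _["bq_alt"] = lba, _["mq_ref"] = lmr, _["mq_alt"] = lma);
}

// ---- Gibbs sampler for the admixture genotype-probability model ----------

// Model: q_i ~ Dirichlet(1); p_kl ~ Beta(1,1); each of the two allele copies
// of individual i at site l draws ancestry z ~ Categorical(q_i) and allele
// a ~ Bernoulli(p_zl); the data enter through the (normalized, linear-scale)
// genotype likelihoods l0/l1/l2. All full conditionals are conjugate.
// Genotype probabilities are accumulated Rao-Blackwellized:
// P(g | p, q) ~ Binom(2, pi_il) * lik_g with pi_il = sum_k q_ik p_kl.
// Uses R's RNG, so set.seed() on the R side fixes the chain.
// [[Rcpp::export]]
List cpp_gibbs_admix(NumericMatrix l0, NumericMatrix l1, NumericMatrix l2,
                     int K, int iters, int burn, int thin) {
  int N = l0.nrow(), L = l0.ncol();
  std::vector<double> p(K * L), q(N * K, 1.0 / K);
  // init p from naive per-site frequency implied by likelihoods
  for (int l = 0; l < L; ++l) {
    double s = 0.0, n = 0.0;
    for (int i = 0; i < N; ++i) {
      double t = l0(i, l) + l1(i, l) + l2(i, l);
      s += (l1(i, l) + 2.0 * l2(i, l)) / t;
      n += 2.0;
    }
    double f = std::min(0.99, std::max(0.01, s / n));
    for (int k = 0; k < K; ++k)
      p[k * L + l] = std::min(0.99, std::max(0.01, f + 0.1 * (unif_rand() - 0.5)));
  }
  int nsamp = 0;
  for (int it = burn + 1; it <= iters; ++it) if ((it - burn) % thin == 0) ++nsamp;
  NumericMatrix p_samples(nsamp, K * L), q_samples(nsamp, N * K);
  NumericVector gprob(N * L * 3);
  std::vector<double> alt_cnt(K * L), tot_cnt(K * L), z_cnt(N * K);
  int isamp = 0;
  for (int it = 1; it <= iters; ++it) {
    std::fill(alt_cnt.begin(), alt_cnt.end(), 0.0);
    std::fill(tot_cnt.begin(), tot_cnt.end(), 0.0);
    std::fill(z_cnt.begin(), z_cnt.end(), 0.0);
    bool record = it > burn && (it - burn) % thin == 0;
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        double pi = 0.0;
        for (int k = 0; k < K; ++k) pi += q[i * K + k] * p[k * L + l];
        double w0 = l0(i, l) * (1.0 - pi) * (1.0 - pi);
        double w1 = l1(i, l) * 2.0 * pi * (1.0 - pi);
        double w2 = l2(i, l) * pi * pi;
        double tot = w0 + w1 + w2;
        if (record) {
          gprob[(0L * N + i) * L + l] += w0 / tot;
          gprob[(1L * N + i) * L + l] += w1 / tot;
          gprob[(2L * N + i) * L + l] += w2 / tot;
        }
        // sample genotype, then per-copy ancestry given its allele
        double u = unif_rand() * tot;
        int g = u < w0 ? 0 : (u < w0 + w1 ? 1 : 2);
        for (int copy = 0; copy < 2; ++copy) {
          int a = g == 2 ? 1 : (g == 0 ? 0 : (copy == 0 ? 1 : 0));
          double zden = 0.0;
          for (int k = 0; k < K; ++k) {
            double pk = p[k * L + l];
            zden += q[i * K + k] * (a ? pk : 1.0 - pk);
          }
          double v = unif_rand() * zden, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) {
            double pk = p[k * L + l];
            acc += q[i * K + k] * (a ? pk : 1.0 - pk);
            if (v <= acc) { z = k; break; }
          }
          z_cnt[i * K + z] += 1.0;
          tot_cnt[z * L + l] += 1.0;
          if (a) alt_cnt[z * L + l] += 1.0;
        }
      }
      // q_i | z ~ Dirichlet(1 + counts)
      double qs = 0.0;
      for (int k = 0; k < K; ++k) {
        q[i * K + k] = R::rgamma(1.0 + z_cnt[i * K + k], 1.0);
        qs += q[i * K + k];
      }
      for (int k = 0; k < K; ++k) q[i * K + k] /= qs;
    }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        p[k * L + l] = R::rbeta(1.0 + alt_cnt[k * L + l],
                                1.0 + tot_cnt[k * L + l] - alt_cnt[k * L + l]);
    if (record) {
      for (int j = 0; j < K * L; ++j) p_samples(isamp, j) = p[j];
      for (int j = 0; j < N * K; ++j) q_samples(isamp, j) = q[j];
      ++isamp;
    }
  }
  for (R_xlen_t j = 0; j < gprob.size(); ++j) gprob[j] /= nsamp;
  gprob.attr("dim") = IntegerVector::create(L, N, 3);  // filled as [l, i, g]
  return List::create(_["gprob"] = gprob, _["p_samples"] = p_samples,
                      _["q_samples"] = q_samples, _["n_samples"] = nsamp);
}
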