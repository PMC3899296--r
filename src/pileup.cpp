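#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <tuple>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Base encoding: A=0, C=1, G=2, T=3, other=-1.
static inline int base_idx(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct Obs {
  int rp;    // 0-based reference position
  int qp;    // 0-based offset within SEQ (includes soft-clipped bases)
  int b;     // base index 0..3, -1 for N
  int q;     // phred quality
  bool drop; // removed by mate-overlap dedup
};

struct EvKey {
  int type; // 1 insertion, 2 deletion
  int pos;  // 1-based: first deleted base (del) / anchor base (ins)
  int len;
  std::string seq;
  bool operator<(const EvKey& o) const {
    return std::tie(type, pos, len, seq) < std::tie(o.type, o.pos, o.len, o.seq);
  }
};

// Walk one alignment record, filling per-base observations and
// incrementing indel/clip evidence arrays.
static void walk_read(const char* seq, const char* qual, const char* cig,
                      int pos1, int L,
                      std::vector<Obs>& obs,
                      std::vector<int>& ins_sup, std::vector<int>& del_sup,
                      std::vector<int>& clip_lead, std::vector<int>& clip_trail,
                      std::map<EvKey, int>& events) {
  int rp = pos1 - 1; // 0-based ref cursor
  int qp = 0;
  int qlen = (int) std::strlen(seq);
  bool seen_m = false;
  const char* p = cig;
  while (*p) {
    int len = 0;
    while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); ++p; }
    char op = *p ? *p++ : '\0';
    if (op == 'M' || op == '=' || op == 'X') {
      for (int k = 0; k < len; ++k) {
        if (rp >= 0 && rp < L && qp < qlen) {
          Obs o; o.rp = rp; o.qp = qp; o.b = base_idx(seq[qp]);
          o.q = (int) qual[qp] - 33; o.drop = false;
          obs.push_back(o);
        }
        ++rp; ++qp;
      }
      seen_m = true;
    } else if (op == 'I') {
      if (seen_m && rp - 1 >= 0 && rp - 1 < L) {
        ins_sup[rp - 1]++;
        EvKey k; k.type = 1; k.pos = rp; k.len = len;
        k.seq = std::string(seq + qp, std::min(len, qlen - qp));
        events[k]++;
      }
      qp += len;
    } else if (op == 'D' || op == 'N') {
      if (op == 'D') {
        for (int k = 0; k < len; ++k)
          if (rp + k >= 0 && rp + k < L) del_sup[rp + k]++;
        EvKey k; k.type = 2; k.pos = rp + 1; k.len = len; k.seq = "";
        events[k]++;
      }
      rp += len;
    } else if (op == 'S') {
      if (!seen_m) {
        if (pos1 - 1 >= 0 && pos1 - 1 < L) clip_lead[pos1 - 1]++;
      } else {
        if (rp >= 0 && rp < L) clip_trail[rp]++;
      }
      qp += len;
    } // H, P: consume nothing we track
  }
}

// Core pileup over one contig. Reads are given with SEQ/QUAL in SAM
// (reference-forward) orientation. `mate` holds the 0-based index of a
// read's mate on the same contig (-1 if none); overlapping mate bases are
// counted once, the higher base quality winning (tie: first record).
// [[Rcpp::export]]
List pileup_core(CharacterVector seqs, CharacterVector quals,
                 CharacterVector cigars, IntegerVector pos,
                 IntegerVector strand, IntegerVector mapq,
                 IntegerVector mate, LogicalVector unmapped,
                 std::string refseq, int min_mapq, int min_baseq) {
  int n = seqs.size();
  int L = (int) refseq.size();
  std::vector<int> ref(L);
  for (int i = 0; i < L; ++i) ref[i] = base_idx(refseq[i]);

  IntegerMatrix counts(L, 8);   // columns: (base A,C,G,T) x (fwd, rev)
  NumericMatrix qsum(L, 4);
  std::vector<int> ins_sup(L, 0), del_sup(L, 0), clip_lead(L, 0), clip_trail(L, 0);
  std::map<EvKey, int> events;
  std::vector<int> m_pos, m_base, m_strand, m_off, m_qual;
  int max_readlen = 0;

  std::vector<bool> done(n, false);
  std::vector<Obs> obs1, obs2;
  obs1.reserve(256); obs2.reserve(256);

  for (int i = 0; i < n; ++i) {
    if (done[i]) continue;
    done[i] = true;
    if (unmapped[i] || mapq[i] < min_mapq) continue;
    const char* s1 = CHAR(STRING_ELT(seqs, i));
    const char* q1 = CHAR(STRING_ELT(quals, i));
    int rl1 = (int) std::strlen(s1);
    if (rl1 > max_readlen) max_readlen = rl1;
    obs1.clear();
    walk_read(s1, q1, CHAR(STRING_ELT(cigars, i)), pos[i], L,
              obs1, ins_sup, del_sup, clip_lead, clip_trail, events);

    int j = mate[i];
    bool have_mate = (j >= 0 && j < n && !done[j] && !unmapped[j] && mapq[j] >= min_mapq);
    int rl2 = 0;
    if (j >= 0 && j < n) done[j] = true;
    if (have_mate) {
      const char* s2 = CHAR(STRING_ELT(seqs, j));
      const char* q2 = CHAR(STRING_ELT(quals, j));
      rl2 = (int) std::strlen(s2);
      if (rl2 > max_readlen) max_readlen = rl2;
      obs2.clear();
      walk_read(s2, q2, CHAR(STRING_ELT(cigars, j)), pos[j], L,
                obs2, ins_sup, del_sup, clip_lead, clip_trail, events);
      // dedup overlap on matched bases
      std::unordered_map<int, int> at;
      at.reserve(obs1.size() * 2);
      for (size_t k = 0; k < obs1.size(); ++k) at[obs1[k].rp] = (int) k;
      for (size_t k = 0; k < obs2.size(); ++k) {
        std::unordered_map<int, int>::iterator it = at.find(obs2[k].rp);
        if (it != at.end()) {
          if (obs2[k].q > obs1[it->second].q) obs1[it->second].drop = true;
          else obs2[k].drop = true;
        }
      }
    }

    for (int which = 0; which < (have_mate ? 2 : 1); ++which) {
      std::vector<Obs>& ob = (which == 0) ? obs1 : obs2;
      int idx = (which == 0) ? i : j;
      int rl = (which == 0) ? rl1 : rl2;
      int st = strand[idx];
      for (size_t k = 0; k < ob.size(); ++k) {
        const Obs& o = ob[k];
        if (o.drop || o.b < 0 || o.q < min_baseq) continue;
        counts(o.rp, o.b * 2 + st)++;
        qsum(o.rp, o.b) += o.q;
        if (o.b != ref[o.rp]) {
          int off = o.qp < rl - 1 - o.qp ? o.qp : rl - 1 - o.qp;
          m_pos.push_back(o.rp + 1);
          m_base.push_back(o.b + 1);
          m_strand.push_back(st);
          m_off.push_back(off);
          m_qual.push_back(o.q);
        }
      }
    }
  }

  int ne = (int) events.size();
  IntegerVector ev_type(ne), ev_pos(ne), ev_len(ne), ev_sup(ne);
  CharacterVector ev_seq(ne);
  int k = 0;
  for (std::map<EvKey, int>::iterator it = events.begin(); it != events.end(); ++it, ++k) {
    ev_type[k] = it->first.type; ev_pos[k] = it->first.pos;
    ev_len[k] = it->first.len; ev_seq[k] = it->first.seq;
    ev_sup[k] = it->second;
  }

  return List::create(
    _["counts"] = counts, _["qsum"] = qsum,
    _["ins_support"] = wrap(ins_sup), _["del_support"] = wrap(del_sup),
    _["clip_lead"] = wrap(clip_lead), _["clip_trail"] = wrap(clip_trail),
    _["mism_pos"] = wrap(m_pos), _["mism_base"] = wrap(m_base),
    _["mism_strand"] = wrap(m_strand), _["mism_offset"] = wrap(m_off),
    _["mism_qual"] = wrap(m_qual),
    _["ev_type"] = ev_type, _["ev_pos"] = ev_pos, _["ev_len"] = ev_len,
    _["ev_seq"] = ev_seq, _["ev_support"] = ev_sup,
    _["read_length"] = max_readlen);
}

// Reference bases consumed by each CIGAR string (M/=/X/D/N).
// [[Rcpp::export]]
IntegerVector cigar_ref_len(CharacterVector cigars) {
  int n = cigars.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* p = CHAR(STRING_ELT(cigars, i));
    int tot = 0;
    while (*p) {
      int len = 0;
      while (*p >= '0' && *p <= '9') { len = len * 10 + (*p - '0'); ++p; }
      char op = *p ? *p++ : '\0';
      if (op == 'M' || op == '=' || op == 'X' || op == 'D' || op == 'N') tot += len;
    }
    out[i] = tot;
  }
  return out;
}

// Reverse complement (ACGTN, case-preserving for upper case input).
// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int) std::strlen(s);
    buf.assign(len, 'N');
    for (int k = 0; k < len; ++k) {
      char c = s[len - 1 - k], r;
      switch (c) {
      case 'A': r = 'T'; break; case 'C': r = 'G'; break;
      case 'G': r = 'C'; break; case 'T': r = 'A'; break;
      case 'a': r = 't'; break; case 'c': r = 'g'; break;
      case 'g': r = 'c'; break; case 't': r = 'a'; break;
      default: r = 'N';
      }
      buf[k] = r;
    }
    out[i] = buf;
  }
  return out;
}
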