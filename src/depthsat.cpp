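#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// ---- small sequence utilities ------------------------------------------

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) c = comp(c);
    return r;
}

static inline bool clean_acgt(const std::string &s) {
    for (char c : s)
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
    return true;
}

// canonical form: lexicographically smaller of k-mer and its reverse complement
static inline std::string canon(const std::string &s) {
    std::string r = revcomp(s);
    return (r < s) ? r : s;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        out[i] = revcomp(as<std::string>(seqs[i]));
    if (seqs.hasAttribute("names")) out.names() = seqs.names();
    return out;
}

// ---- k-mer counting -----------------------------------------------------

static void count_into(std::unordered_map<std::string, int> &tab,
                       CharacterVector reads, int k) {
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        std::string s = as<std::string>(reads[i]);
        if ((int)s.size() < k) continue;
        for (size_t j = 0; j + k <= s.size(); ++j) {
            std::string km = s.substr(j, k);
            if (!clean_acgt(km)) continue;
            ++tab[canon(km)];
        }
    }
}

// [[Rcpp::export]]
IntegerVector count_kmers_cpp(CharacterVector reads, int k) {
    std::unordered_map<std::string, int> tab;
    count_into(tab, reads, k);
    std::vector<std::string> keys;
    keys.reserve(tab.size());
    for (auto &p : tab) keys.push_back(p.first);
    std::sort(keys.begin(), keys.end());
    IntegerVector out(keys.size());
    CharacterVector nm(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) {
        nm[i] = keys[i];
        out[i] = tab[keys[i]];
    }
    out.names() = nm;
    return out;
}

// ---- de Bruijn unitig assembly -----------------------------------------

typedef std::unordered_set<std::string> KmerSet;

// bases extending oriented k-mer x forward by one
static int successors(const KmerSet &S, const std::string &x, char *hits) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int n = 0;
    std::string cand = x.substr(1) + "A";
    for (int b = 0; b < 4; ++b) {
        cand[cand.size() - 1] = bases[b];
        if (S.count(canon(cand))) hits[n++] = bases[b];
    }
    return n;
}

static int predecessors(const KmerSet &S, const std::string &x, char *hits) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int n = 0;
    std::string cand = "A" + x.substr(0, x.size() - 1);
    for (int b = 0; b < 4; ++b) {
        cand[0] = bases[b];
        if (S.count(canon(cand))) hits[n++] = bases[b];
    }
    return n;
}

// a unitig starts at x if it cannot be uniquely extended backwards
static bool is_start(const KmerSet &S, const std::string &x) {
    char hits[4];
    int np = predecessors(S, x, hits);
    if (np != 1) return true;
    std::string pred = std::string(1, hits[0]) + x.substr(0, x.size() - 1);
    char sh[4];
    return successors(S, pred, sh) != 1;
}

// walk a maximal non-branching path from oriented start; marks canonical
// nodes visited
static std::string walk(const KmerSet &S, KmerSet &visited,
                        const std::string &start) {
    std::string contig = start;
    std::string cur = start;
    visited.insert(canon(cur));
    char hits[4];
    while (true) {
        int ns = successors(S, cur, hits);
        if (ns != 1) break;
        std::string nxt = cur.substr(1) + std::string(1, hits[0]);
        char ph[4];
        if (predecessors(S, nxt, ph) != 1) break;
        if (visited.count(canon(nxt))) break; // cycle closure
        visited.insert(canon(nxt));
        contig += hits[0];
        cur = nxt;
    }
    return contig;
}

// [[Rcpp::export]]
CharacterVector assemble_dbg_cpp(CharacterVector reads, int k,
                                 int coverage_cutoff, int min_contig_length) {
    std::unordered_map<std::string, int> tab;
    count_into(tab, reads, k);
    KmerSet S;
    for (auto &p : tab)
        if (p.second >= coverage_cutoff) S.insert(p.first);
    tab.clear();

    std::vector<std::string> keys(S.begin(), S.end());
    std::sort(keys.begin(), keys.end());

    KmerSet visited;
    std::vector<std::string> contigs;
    for (const std::string &km : keys) {
        for (int o = 0; o < 2; ++o) {
            std::string x = (o == 0) ? km : revcomp(km);
            if (visited.count(km)) break;
            if (is_start(S, x)) contigs.push_back(walk(S, visited, x));
        }
    }
    // remaining nodes lie on perfect cycles
    for (const std::string &km : keys)
        if (!visited.count(km)) contigs.push_back(walk(S, visited, km));

    std::vector<std::string> kept;
    for (std::string &c : contigs) {
        if ((int)c.size() < min_contig_length) continue;
        std::string r = revcomp(c);
        kept.push_back((r < c) ? r : c); // deterministic orientation
    }
    std::sort(kept.begin(), kept.end(),
              [](const std::string &a, const std::string &b) {
                  return a.size() != b.size() ? a.size() > b.size() : a < b;
              });
    return wrap(kept);
}

// ---- locus clustering: contigs sharing >= 1 canonical k-mer -------------

static int uf_find(std::vector<int> &par, int i) {
    while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
    return i;
}

// [[Rcpp::export]]
IntegerVector cluster_loci_cpp(CharacterVector contigs, int k) {
    int n = contigs.size();
    std::vector<int> par(n);
    for (int i = 0; i < n; ++i) par[i] = i;
    std::unordered_map<std::string, int> first_seen;
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(contigs[i]);
        if ((int)s.size() < k) continue;
        for (size_t j = 0; j + k <= s.size(); ++j) {
            std::string km = s.substr(j, k);
            if (!clean_acgt(km)) continue;
            km = canon(km);
            auto it = first_seen.find(km);
            if (it == first_seen.end()) first_seen[km] = i;
            else {
                int a = uf_find(par, i), b = uf_find(par, it->second);
                if (a != b) par[std::max(a, b)] = std::min(a, b);
            }
        }
    }
    // stable 1-based component labels in order of first appearance
    IntegerVector out(n);
    std::unordered_map<int, int> relabel;
    int next_id = 0;
    for (int i = 0; i < n; ++i) {
        int root = uf_find(par, i);
        auto it = relabel.find(root);
        if (it == relabel.end()) relabel[root] = ++next_id;
        out[i] = relabel[root];
    }
    return out;
}

// ---- read filtration flags ---------------------------------------------

// 0 = passes sequence rules, 1 = adapter, 2 = low complexity
// adapter rule: any configured adapter as exact substring, or a read suffix
// matching an adapter prefix of length >= 12 with <= 1 mismatch (read-through)
// low-complexity rule: dominant base >= dom_frac of non-N positions, or a
// homopolymer run >= run_frac * length, or > max_n_frac N
// [[Rcpp::export]]
IntegerVector seq_filter_flags_cpp(CharacterVector seqs, CharacterVector adapters,
                                   double dom_frac, double run_frac,
                                   double max_n_frac) {
    std::vector<std::string> ads;
    for (R_xlen_t a = 0; a < adapters.size(); ++a)
        ads.push_back(as<std::string>(adapters[a]));
    IntegerVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        size_t len = s.size();
        bool adapter = false;
        for (const std::string &ad : ads) {
            if (ad.empty()) continue;
            if (s.find(ad) != std::string::npos) { adapter = true; break; }
            size_t maxL = std::min(ad.size() - 1, len);
            for (size_t L = 12; L <= maxL && !adapter; ++L) {
                int mm = 0;
                const char *suf = s.c_str() + (len - L);
                for (size_t j = 0; j < L; ++j)
                    if (suf[j] != ad[j] && ++mm > 1) break;
                if (mm <= 1) adapter = true;
            }
            if (adapter) break;
        }
        if (adapter) { out[i] = 1; continue; }

        int cnt[5] = {0, 0, 0, 0, 0}; // A C G T N/other
        int maxrun = 0, run = 0;
        char prev = 0;
        for (char c : s) {
            switch (c) {
            case 'A': ++cnt[0]; break; case 'C': ++cnt[1]; break;
            case 'G': ++cnt[2]; break; case 'T': ++cnt[3]; break;
            default:  ++cnt[4];
            }
            if (c == prev && c != 'N') ++run; else { run = 1; prev = c; }
            if (run > maxrun) maxrun = run;
        }
        int nn = cnt[0] + cnt[1] + cnt[2] + cnt[3];
        int dom = std::max(std::max(cnt[0], cnt[1]), std::max(cnt[2], cnt[3]));
        bool lowc = (nn > 0 && dom >= dom_frac * nn) ||
                    (len > 0 && maxrun >= run_frac * (double)len) ||
                    (len > 0 && cnt[4] > max_n_frac * (double)len);
        out[i] = lowc ? 2 : 0;
    }
    return out;
}

// ---- exact-word seed screen for the translated search -------------------

// TRUE for each subject sharing at least one exact length-w word with any query
// [[Rcpp::export]]
LogicalVector shares_word_cpp(CharacterVector queries, CharacterVector subjects,
                              int w) {
    std::unordered_set<std::string> words;
    for (R_xlen_t i = 0; i < queries.size(); ++i) {
        std::string q = as<std::string>(queries[i]);
        for (size_t j = 0; j + w <= q.size(); ++j)
            words.insert(q.substr(j, w));
    }
    LogicalVector out(subjects.size());
    for (R_xlen_t i = 0; i < subjects.size(); ++i) {
        std::string s = as<std::string>(subjects[i]);
        bool hit = false;
        for (size_t j = 0; j + w <= s.size() && !hit; ++j)
            if (words.count(s.substr(j, w))) hit = true;
        out[i] = hit;
    }
    return out;
}
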