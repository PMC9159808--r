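#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// CRC-32 (IEEE 802.3 polynomial 0xEDB88320, reflected), table-driven.
// Matches zlib's crc32(). Values returned as doubles: they exceed R's
// 32-bit signed integer range.
// ---------------------------------------------------------------------------

static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void crc_init() {
    if (crc_table_ready) return;
    for (uint32_t i = 0; i < 256; ++i) {
        uint32_t c = i;
        for (int k = 0; k < 8; ++k)
            c = (c & 1u) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
        crc_table[i] = c;
    }
    crc_table_ready = true;
}

static uint32_t crc32_bytes(const char* s, size_t n) {
    crc_init();
    uint32_t c = 0xFFFFFFFFu;
    for (size_t i = 0; i < n; ++i)
        c = crc_table[(c ^ (uint8_t)s[i]) & 0xFFu] ^ (c >> 8);
    return c ^ 0xFFFFFFFFu;
}

// [[Rcpp::export]]
NumericVector cpp_crc32(CharacterVector keys) {
    R_xlen_t n = keys.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* s = CHAR(STRING_ELT(keys, i));
        out[i] = (double) crc32_bytes(s, strlen(s));
    }
    return out;
}

// ---------------------------------------------------------------------------
// Canonical labeling of a small connected vertex- and edge-labelled graph.
//
// A "connected ordering" places vertices one at a time, each adjacent to an
// already-placed vertex. Its code is, per position: the vertex label code,
// then the sorted (placed-position, edge-label) pairs of its back-edges.
// The lexicographically minimal code over all connected orderings is an
// isomorphism invariant; the search branches only on ties, so it is fast
// for the fragment sizes used here (<= 11 atoms).
// ---------------------------------------------------------------------------

struct CanonGraph {
    int n;
    std::vector<int> lab;                              // vertex label codes
    std::vector<std::vector<std::pair<int,int> > > adj; // (neighbour, edge label)
};

struct CanonState {
    const CanonGraph* g;
    std::vector<int> pos;        // vertex -> position, -1 if unplaced
    std::vector<int> order;      // position -> vertex
    std::vector<int> code;       // flattened current code
    std::vector<int> best_code;
    std::vector<int> best_order;
    bool have_best;
};

static void vertex_row(const CanonState& st, int v, std::vector<int>& row) {
    row.clear();
    row.push_back(st.g->lab[v]);
    std::vector<std::pair<int,int> > back;
    const std::vector<std::pair<int,int> >& nb = st.g->adj[v];
    for (size_t i = 0; i < nb.size(); ++i) {
        int p = st.pos[nb[i].first];
        if (p >= 0) back.push_back(std::make_pair(p, nb[i].second));
    }
    std::sort(back.begin(), back.end());
    row.push_back((int) back.size());
    for (size_t i = 0; i < back.size(); ++i) {
        row.push_back(back[i].first);
        row.push_back(back[i].second);
    }
}

// lexicographic compare of code+row extension against best prefix:
// -1 smaller, 0 equal-so-far, +1 larger
static int cmp_prefix(const std::vector<int>& code, const std::vector<int>& row,
                      const std::vector<int>& best) {
    size_t off = code.size();
    for (size_t i = 0; i < row.size(); ++i) {
        size_t j = off + i;
        if (j >= best.size()) return 1; // longer => cannot beat a complete best
        if (row[i] < best[j]) return -1;
        if (row[i] > best[j]) return 1;
    }
    return 0;
}

// `tight` is true while the current code equals the incumbent best code's
// prefix; only then may elementwise comparisons prune (once the path is
// strictly smaller it must be explored to completion).
static void canon_rec(CanonState& st, int placed, bool tight) {
    const CanonGraph& g = *st.g;
    if (placed == g.n) {
        if (!st.have_best || st.code < st.best_code) {
            st.best_code = st.code;
            st.best_order = st.order;
            st.have_best = true;
        }
        return;
    }
    // candidates: unplaced vertices adjacent to the placed set
    // (for placed == 0: every vertex)
    std::vector<int> cand;
    if (placed == 0) {
        for (int v = 0; v < g.n; ++v) cand.push_back(v);
    } else {
        std::vector<char> seen(g.n, 0);
        for (int p = 0; p < placed; ++p) {
            int u = st.order[p];
            for (size_t i = 0; i < g.adj[u].size(); ++i) {
                int w = g.adj[u][i].first;
                if (st.pos[w] < 0 && !seen[w]) { seen[w] = 1; cand.push_back(w); }
            }
        }
    }
    // minimal row among candidates
    std::vector<std::vector<int> > rows(cand.size());
    int best_i = -1;
    for (size_t i = 0; i < cand.size(); ++i) {
        vertex_row(st, cand[i], rows[i]);
        if (best_i < 0 || rows[i] < rows[best_i]) best_i = (int) i;
    }
    const std::vector<int>& minrow = rows[best_i];
    bool child_tight = false;
    if (st.have_best && tight) {
        int c = cmp_prefix(st.code, minrow, st.best_code);
        if (c > 0) return;
        child_tight = (c == 0);
    }
    size_t code_len = st.code.size();
    for (size_t i = 0; i < cand.size(); ++i) {
        if (rows[i] != minrow) continue;
        int v = cand[i];
        st.code.insert(st.code.end(), minrow.begin(), minrow.end());
        st.pos[v] = placed;
        st.order[placed] = v;
        canon_rec(st, placed + 1, child_tight);
        st.pos[v] = -1;
        st.code.resize(code_len);
    }
}

// Run canonicalization; returns order (position -> vertex).
static std::vector<int> canon_order(const CanonGraph& g) {
    CanonState st;
    st.g = &g;
    st.pos.assign(g.n, -1);
    st.order.assign(g.n, -1);
    st.have_best = false;
    canon_rec(st, 0, false);
    return st.best_order;
}

// Build the printable key from label strings and the canonical order.
static std::string build_key(const CanonGraph& g,
                             const std::vector<int>& order,
                             const std::vector<std::string>& lab_str,
                             const std::vector<std::vector<std::pair<int,int> > >& adj_estr_idx,
                             const std::vector<std::string>& elab_str) {
    int n = g.n;
    std::vector<int> pos(n);
    for (int p = 0; p < n; ++p) pos[order[p]] = p;
    std::string key;
    for (int p = 0; p < n; ++p) {
        int v = order[p];
        if (p) key += "|";
        key += lab_str[(size_t) v];
    }
    key += "||";
    std::vector<std::string> edges;
    for (int v = 0; v < n; ++v) {
        for (size_t i = 0; i < adj_estr_idx[v].size(); ++i) {
            int w = adj_estr_idx[v][i].first;
            if (v < w) {
                int a = pos[v], b = pos[w];
                if (a > b) std::swap(a, b);
                std::string e = std::to_string(a) + "-" + std::to_string(b);
                int eli = adj_estr_idx[v][i].second;
                if (eli >= 0) e += ":" + elab_str[(size_t) eli];
                edges.push_back(e);
            }
        }
    }
    std::sort(edges.begin(), edges.end());
    for (size_t i = 0; i < edges.size(); ++i) {
        if (i) key += ",";
        key += edges[i];
    }
    return key;
}

// Canonical order of a whole (connected) labelled graph.
// edges: m x 2, 0-based; lab: per-vertex integer codes ordered like the
// label strings; elab: per-edge integer codes (or -1 for unlabelled).
// [[Rcpp::export]]
IntegerVector cpp_canonical_order(int n, IntegerMatrix edges,
                                  IntegerVector lab, IntegerVector elab) {
    CanonGraph g;
    g.n = n;
    g.lab.assign(lab.begin(), lab.end());
    g.adj.assign(n, std::vector<std::pair<int,int> >());
    for (int e = 0; e < edges.nrow(); ++e) {
        int a = edges(e, 0), b = edges(e, 1);
        int el = (elab.size() > e) ? elab[e] : -1;
        g.adj[a].push_back(std::make_pair(b, el));
        g.adj[b].push_back(std::make_pair(a, el));
    }
    std::vector<int> ord = canon_order(g);
    IntegerVector out(n);
    for (int p = 0; p < n; ++p) out[p] = ord[p] + 1; // 1-based for R
    return out;
}

// Canonical key string for one connected subgraph given global labels.
// [[Rcpp::export]]
CharacterVector cpp_canonical_key(int n, IntegerMatrix edges,
                                  IntegerVector lab, CharacterVector lab_str,
                                  IntegerVector elab, CharacterVector elab_str) {
    CanonGraph g;
    g.n = n;
    g.lab.assign(lab.begin(), lab.end());
    g.adj.assign(n, std::vector<std::pair<int,int> >());
    std::vector<std::vector<std::pair<int,int> > > adj_es(n);
    for (int e = 0; e < edges.nrow(); ++e) {
        int a = edges(e, 0), b = edges(e, 1);
        int el = (elab.size() > e) ? elab[e] : -1;
        g.adj[a].push_back(std::make_pair(b, el));
        g.adj[b].push_back(std::make_pair(a, el));
        adj_es[a].push_back(std::make_pair(b, el));
        adj_es[b].push_back(std::make_pair(a, el));
    }
    std::vector<int> ord = canon_order(g);
    std::vector<std::string> ls(n), es(elab_str.size());
    for (int i = 0; i < n; ++i) ls[i] = as<std::string>(lab_str[i]);
    for (R_xlen_t i = 0; i < elab_str.size(); ++i) es[i] = as<std::string>(elab_str[i]);
    return CharacterVector::create(build_key(g, ord, ls, adj_es, es));
}

// ---------------------------------------------------------------------------
// ESU enumeration of connected vertex-induced subgraphs with
// min_size <= |V| <= max_size, each exactly once, plus canonical keys.
// ---------------------------------------------------------------------------

struct EnumCtx {
    int n;
    std::vector<std::vector<int> > nbr;                 // adjacency lists
    std::vector<std::vector<std::pair<int,int> > > adjE; // (nbr, edge label idx)
    std::vector<int> lab;
    std::vector<std::string> lab_str;
    std::vector<std::string> elab_str;
    int min_size, max_size;
    long cap, count;
    std::vector<std::string> keys;
    std::vector<std::vector<int> > members;
};

static void record_subgraph(EnumCtx& ctx, const std::vector<int>& S) {
    if (++ctx.count > ctx.cap)
        stop("fragment enumeration exceeded cap of %ld subgraphs", ctx.cap);
    int k = (int) S.size();
    // build local subgraph
    std::vector<int> local(ctx.n, -1);
    for (int i = 0; i < k; ++i) local[S[i]] = i;
    CanonGraph g;
    g.n = k;
    g.lab.resize(k);
    g.adj.assign(k, std::vector<std::pair<int,int> >());
    std::vector<std::vector<std::pair<int,int> > > adj_es(k);
    std::vector<std::string> ls(k);
    for (int i = 0; i < k; ++i) {
        int v = S[i];
        g.lab[i] = ctx.lab[v];
        ls[i] = ctx.lab_str[v];
        for (size_t j = 0; j < ctx.adjE[v].size(); ++j) {
            int w = ctx.adjE[v][j].first;
            int li = local[w];
            if (li >= 0) {
                g.adj[i].push_back(std::make_pair(li, ctx.adjE[v][j].second));
                adj_es[i].push_back(std::make_pair(li, ctx.adjE[v][j].second));
            }
        }
    }
    std::vector<int> ord = canon_order(g);
    ctx.keys.push_back(build_key(g, ord, ls, adj_es, ctx.elab_str));
    ctx.members.push_back(S);
}

static void esu_extend(EnumCtx& ctx, int v, std::vector<int>& S,
                       std::vector<int> ext, std::vector<char>& inS,
                       std::vector<char>& nbrS) {
    if ((int) S.size() >= ctx.min_size) record_subgraph(ctx, S);
    if ((int) S.size() == ctx.max_size) return;
    while (!ext.empty()) {
        int u = ext.back();
        ext.pop_back();
        std::vector<int> ext2 = ext;
        // exclusive neighbours of u: > v, not in S, not already neighbours of S
        for (size_t i = 0; i < ctx.nbr[u].size(); ++i) {
            int w = ctx.nbr[u][i];
            if (w > v && !inS[w] && !nbrS[w]) ext2.push_back(w);
        }
        S.push_back(u);
        inS[u] = 1;
        // update nbrS with u's neighbourhood
        std::vector<int> touched;
        for (size_t i = 0; i < ctx.nbr[u].size(); ++i) {
            int w = ctx.nbr[u][i];
            if (!nbrS[w]) { nbrS[w] = 1; touched.push_back(w); }
        }
        esu_extend(ctx, v, S, ext2, inS, nbrS);
        for (size_t i = 0; i < touched.size(); ++i) nbrS[touched[i]] = 0;
        inS[u] = 0;
        S.pop_back();
    }
}

// [[Rcpp::export]]
List cpp_enumerate_fragments(int n, IntegerMatrix edges,
                             IntegerVector lab, CharacterVector lab_str,
                             IntegerVector elab, CharacterVector elab_str,
                             int min_size, int max_size, double cap) {
    EnumCtx ctx;
    ctx.n = n;
    ctx.nbr.assign(n, std::vector<int>());
    ctx.adjE.assign(n, std::vector<std::pair<int,int> >());
    for (int e = 0; e < edges.nrow(); ++e) {
        int a = edges(e, 0), b = edges(e, 1);
        int el = (elab.size() > e) ? elab[e] : -1;
        ctx.nbr[a].push_back(b);
        ctx.nbr[b].push_back(a);
        ctx.adjE[a].push_back(std::make_pair(b, el));
        ctx.adjE[b].push_back(std::make_pair(a, el));
    }
    ctx.lab.assign(lab.begin(), lab.end());
    ctx.lab_str.resize(n);
    for (int i = 0; i < n; ++i) ctx.lab_str[i] = as<std::string>(lab_str[i]);
    ctx.elab_str.resize(elab_str.size());
    for (R_xlen_t i = 0; i < elab_str.size(); ++i)
        ctx.elab_str[i] = as<std::string>(elab_str[i]);
    ctx.min_size = min_size;
    ctx.max_size = max_size;
    ctx.cap = (long) cap;
    ctx.count = 0;

    std::vector<char> inS(n, 0), nbrS(n, 0);
    for (int v = 0; v < n; ++v) {
        std::vector<int> S;
        S.push_back(v);
        inS[v] = 1;
        std::vector<int> ext;
        std::vector<int> touched;
        for (size_t i = 0; i < ctx.nbr[v].size(); ++i) {
            int w = ctx.nbr[v][i];
            if (!nbrS[w]) { nbrS[w] = 1; touched.push_back(w); }
            if (w > v) ext.push_back(w);
        }
        esu_extend(ctx, v, S, ext, inS, nbrS);
        for (size_t i = 0; i < touched.size(); ++i) nbrS[touched[i]] = 0;
        inS[v] = 0;
    }

    CharacterVector keys(ctx.keys.size());
    List members(ctx.members.size());
    for (size_t i = 0; i < ctx.keys.size(); ++i) {
        keys[i] = ctx.keys[i];
        IntegerVector m(ctx.members[i].size());
        for (size_t j = 0; j < ctx.members[i].size(); ++j)
            m[j] = ctx.members[i][j] + 1; // 1-based
        members[i] = m;
    }
    return List::create(_["keys"] = keys, _["atoms"] = members);
}
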