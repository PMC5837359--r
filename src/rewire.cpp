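#include <Rcpp.h>
#include <vector>
#include <set>
using namespace Rcpp;

// BFS over adjacency sets; true when every node is reachable from node 0.
static bool is_connected(const std::vector<std::set<int> >& adj) {
    int n = adj.size();
    if (n == 0) return true;
    std::vector<char> seen(n, 0);
    std::vector<int> stack;
    stack.push_back(0);
    seen[0] = 1;
    int count = 1;
    while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        for (std::set<int>::const_iterator it = adj[v].begin(); it != adj[v].end(); ++it) {
            if (!seen[*it]) {
                seen[*it] = 1;
                ++count;
                stack.push_back(*it);
            }
        }
    }
    return count == n;
}

//' @noRd
// [[Rcpp::export(name = ".rewire_degseq_cpp")]]
IntegerMatrix rewire_degseq_cpp(IntegerMatrix edges, int n_nodes, int n_attempts) {
    int m = edges.nrow();
    std::vector<int> ea(m), eb(m);
    std::vector<std::set<int> > adj(n_nodes);
    for (int e = 0; e < m; ++e) {
        ea[e] = edges(e, 0);
        eb[e] = edges(e, 1);
        adj[ea[e]].insert(eb[e]);
        adj[eb[e]].insert(ea[e]);
    }
    if (m < 2) {
        return edges;
    }
    RNGScope scope;
    for (int t = 0; t < n_attempts; ++t) {
        int e1 = (int)(unif_rand() * m);
        int e2 = (int)(unif_rand() * m);
        if (e1 >= m) e1 = m - 1;
        if (e2 >= m) e2 = m - 1;
        if (e1 == e2) continue;
        int a = ea[e1], b = eb[e1];
        int c = ea[e2], d = eb[e2];
        if (unif_rand() < 0.5) { int tmp = c; c = d; d = tmp; }
        // proposed swap: (a,b),(c,d) -> (a,d),(c,b)
        if (a == d || c == b || a == c || b == d) continue;
        if (adj[a].count(d) || adj[c].count(b)) continue;
        // apply
        adj[a].erase(b); adj[b].erase(a);
        adj[c].erase(d); adj[d].erase(c);
        adj[a].insert(d); adj[d].insert(a);
        adj[c].insert(b); adj[b].insert(c);
        if (!is_connected(adj)) {
            // revert
            adj[a].erase(d); adj[d].erase(a);
            adj[c].erase(b); adj[b].erase(c);
            adj[a].insert(b); adj[b].insert(a);
            adj[c].insert(d); adj[d].insert(c);
            continue;
        }
        eb[e1] = d;
        ea[e2] = c; eb[e2] = b;
    }
    IntegerMatrix out(m, 2);
    for (int e = 0; e < m; ++e) {
        out(e, 0) = ea[e];
        out(e, 1) = eb[e];
    }
    return out;
}
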