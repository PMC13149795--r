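#include <R.h>
#include <Rinternals.h>
#include <string.h>

/* Minimum-change (unordered, uniform-cost) parsimony scoring.
 *
 * Trees are rooted and given as a parent vector: nodes are 1..M, nodes
 * 1..nleaf are tips, parent[root] == 0.  Polytomies are allowed, and the
 * root may itself be a tip (a tree oriented away from one leaf).
 *
 * Scoring uses the counting form of Hartigan's generalisation of Fitch's
 * algorithm, which is exact on multifurcating trees with ambiguous
 * (set-valued) tips: under unit costs the Sankoff cost vector of any
 * subtree, seen through its root edge, takes only the values m and m+1,
 * so each child is fully described by (m, B) with B the set of states
 * attaining m.  A node combining children then has
 *   m = sum(m_c) + (n_children - K),  K = max over states of the number
 * of children whose B contains the state, and B = the argmax set.
 * A tip contributes its own allowed-state set as one extra part.
 *
 * State sets are bit masks (up to 32 states per character).
 */

static void build_children(const int *parent, int M, int *ptr, int *ci, int *root)
{
    int i, p;
    int *cnt = (int *) R_alloc(M, sizeof(int));
    memset(cnt, 0, M * sizeof(int));
    *root = -1;
    for (i = 0; i < M; i++) {
        p = parent[i];
        if (p == 0) *root = i;
        else cnt[p - 1]++;
    }
    if (*root < 0) error("tree has no root (no zero entry in parent vector)");
    ptr[0] = 0;
    for (i = 0; i < M; i++) ptr[i + 1] = ptr[i] + cnt[i];
    memset(cnt, 0, M * sizeof(int));
    for (i = 0; i < M; i++) {
        p = parent[i];
        if (p != 0) ci[ptr[p - 1] + cnt[p - 1]++] = i;
    }
}

/* reverse preorder == a valid postorder (children before parents) */
static void postorder(const int *ptr, const int *ci, int M, int root, int *po)
{
    int *stack = (int *) R_alloc(M, sizeof(int));
    int top = 0, k = M, v, j;
    stack[top++] = root;
    while (top > 0) {
        v = stack[--top];
        po[--k] = v;
        for (j = ptr[v]; j < ptr[v + 1]; j++) stack[top++] = ci[j];
    }
    if (k != 0) error("parent vector does not describe a single connected tree");
}

/* what: 0 = total steps only, 1 = per-character steps,
 *       2 = per-character steps + downpass state sets */
SEXP C_fitch(SEXP Sparent, SEXP Snleaf, SEXP Smasks, SEXP Stips, SEXP Swhat)
{
    int M = LENGTH(Sparent);
    int nleaf = asInteger(Snleaf);
    int what = asInteger(Swhat);
    int nchar = nrows(Smasks);
    const int *parent = INTEGER(Sparent);
    const int *masks = INTEGER(Smasks);
    const int *tips = INTEGER(Stips);
    int *ptr = (int *) R_alloc(M + 1, sizeof(int));
    int *ci = (int *) R_alloc(M, sizeof(int));
    int *po = (int *) R_alloc(M, sizeof(int));
    int *set = (int *) R_alloc(M, sizeof(int));
    int root, c, i, j, v, s, nparts, K, bits, best, total = 0;
    int cnt[32];
    SEXP Ssteps = R_NilValue, Ssets = R_NilValue, ans;
    int *steps = NULL, *sets = NULL;

    build_children(parent, M, ptr, ci, &root);
    postorder(ptr, ci, M, root, po);

    if (what >= 1) {
        Ssteps = PROTECT(allocVector(INTSXP, nchar));
        steps = INTEGER(Ssteps);
    }
    if (what >= 2) {
        Ssets = PROTECT(allocMatrix(INTSXP, nchar, M));
        sets = INTEGER(Ssets);
    }

    for (c = 0; c < nchar; c++) {
        int st = 0;
        for (i = 0; i < M; i++) {
            int unon, b;
            v = po[i];
            if (v < nleaf && ptr[v + 1] == ptr[v]) {      /* plain tip */
                set[v] = masks[c + (size_t) nchar * (tips[v] - 1)];
                if (set[v] == 0)
                    error("tip %d has an empty state set for character %d",
                          v + 1, c + 1);
                continue;
            }
            nparts = 0;
            unon = 0;
            if (v < nleaf) {                               /* tip used as root */
                bits = masks[c + (size_t) nchar * (tips[v] - 1)];
                b = bits & ~unon;
                while (b) { cnt[__builtin_ctz(b)] = 0; b &= b - 1; }
                unon |= bits;
                while (bits) { cnt[__builtin_ctz(bits)]++; bits &= bits - 1; }
                nparts++;
            }
            for (j = ptr[v]; j < ptr[v + 1]; j++) {
                bits = set[ci[j]];
                b = bits & ~unon;
                while (b) { cnt[__builtin_ctz(b)] = 0; b &= b - 1; }
                unon |= bits;
                while (bits) { cnt[__builtin_ctz(bits)]++; bits &= bits - 1; }
                nparts++;
            }
            K = 0;
            b = unon;
            while (b) {
                s = __builtin_ctz(b);
                if (cnt[s] > K) K = cnt[s];
                b &= b - 1;
            }
            best = 0;
            b = unon;
            while (b) {
                s = __builtin_ctz(b);
                if (cnt[s] == K) best |= (1 << s);
                b &= b - 1;
            }
            st += nparts - K;
            set[v] = best;
        }
        total += st;
        if (steps) steps[c] = st;
        if (sets) for (i = 0; i < M; i++) sets[c + (size_t) nchar * i] = set[i];
    }

    if (what == 0) return ScalarInteger(total);
    if (what == 1) {
        UNPROTECT(1);
        return Ssteps;
    }
    ans = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(ans, 0, Ssteps);
    SET_VECTOR_ELT(ans, 1, Ssets);
    UNPROTECT(3);
    return ans;
}

/* Orient an unrooted tree (edge matrix, nodes 1..M) away from `root`,
 * returning a parent vector (root gets parent 0).  Used to score the
 * edge-matrix trees handled by the heuristic search. */
SEXP C_orient(SEXP Sedges, SEXP Snnode, SEXP Sroot)
{
    int ne = nrows(Sedges);
    int M = asInteger(Snnode);
    int root = asInteger(Sroot) - 1;
    const int *ea = INTEGER(Sedges);
    const int *eb = ea + ne;
    int *deg = (int *) R_alloc(M, sizeof(int));
    int *ptr = (int *) R_alloc(M + 1, sizeof(int));
    int *adj = (int *) R_alloc(2 * ne, sizeof(int));
    int *pos = (int *) R_alloc(M, sizeof(int));
    int *stack = (int *) R_alloc(M, sizeof(int));
    int i, a, b, v, w, j, top = 0, seen = 0;
    SEXP Sparent = PROTECT(allocVector(INTSXP, M));
    int *parent = INTEGER(Sparent);

    memset(deg, 0, M * sizeof(int));
    for (i = 0; i < ne; i++) {
        a = ea[i] - 1; b = eb[i] - 1;
        if (a < 0 || a >= M || b < 0 || b >= M)
            error("edge matrix refers to node outside 1..%d", M);
        deg[a]++; deg[b]++;
    }
    ptr[0] = 0;
    for (i = 0; i < M; i++) ptr[i + 1] = ptr[i] + deg[i];
    memset(pos, 0, M * sizeof(int));
    for (i = 0; i < ne; i++) {
        a = ea[i] - 1; b = eb[i] - 1;
        adj[ptr[a] + pos[a]++] = b;
        adj[ptr[b] + pos[b]++] = a;
    }
    for (i = 0; i < M; i++) parent[i] = -1;
    parent[root] = 0;
    stack[top++] = root;
    while (top > 0) {
        v = stack[--top];
        seen++;
        for (j = ptr[v]; j < ptr[v + 1]; j++) {
            w = adj[j];
            if (parent[w] == -1) {
                parent[w] = v + 1;
                stack[top++] = w;
            }
        }
    }
    if (seen != M) error("edge matrix is not a connected tree on %d nodes", M);
    UNPROTECT(1);
    return Sparent;
}
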