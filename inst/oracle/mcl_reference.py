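"""Reference Markov Clustering used as an independent cross-check.

Reads a symmetric weighted adjacency matrix from a TSV (with row/column
ids in the first row/column), runs textbook MCL (self-loops = max incident
weight, column normalisation, expansion/inflation with pruning) and prints
one line per node: `<node>\t<cluster>`.

Usage: python mcl_reference.py <matrix.tsv> <inflation> [max_iter] [prune] [tol]
"""
import sys

import numpy as np


def mcl(M, inflation, max_iter=100, prune=1e-5, tol=1e-6):
    n = M.shape[0]
    loops = M.max(axis=0)
    loops[loops <= 0] = 1.0
    M = M.copy()
    np.fill_diagonal(M, loops)
    M = M / M.sum(axis=0, keepdims=True)
    for _ in range(max_iter):
        new = M @ M
        new = new ** inflation
        new[new < prune] = 0.0
        cs = new.sum(axis=0, keepdims=True)
        cs[cs == 0] = 1.0
        new = new / cs
        delta = np.abs(new - M).max()
        M = new
        if delta < tol:
            break
    # connected components of the non-zero structure
    adj = (M > prune) | (M.T > prune)
    labels = -np.ones(n, dtype=int)
    cur = 0
    for i in range(n):
        if labels[i] >= 0:
            continue
        stack = [i]
        labels[i] = cur
        while stack:
            u = stack.pop()
            for v in np.where(adj[u])[0]:
                if labels[v] < 0:
                    labels[v] = cur
                    stack.append(v)
        cur += 1
    return labels


def main():
    path = sys.argv[1]
    inflation = float(sys.argv[2])
    max_iter = int(sys.argv[3]) if len(sys.argv) > 3 else 100
    prune = float(sys.argv[4]) if len(sys.argv) > 4 else 1e-5
    tol = float(sys.argv[5]) if len(sys.argv) > 5 else 1e-6
    with open(path) as fh:
        header = fh.readline().rstrip("\n").split("\t")[1:]
        rows = [line.rstrip("\n").split("\t") for line in fh if line.strip()]
    ids = [r[0] for r in rows]
    assert ids == header, "matrix must be symmetric with matching ids"
    M = np.array([[float(x) for x in r[1:]] for r in rows])
    labels = mcl(M, inflation, max_iter, prune, tol)
    for node, lab in zip(ids, labels):
        sys.stdout.write(f"{node}\t{lab}\n")


if __name__ == "__main__":
    main()
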