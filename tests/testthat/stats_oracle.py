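"""Reference statistics for cross-validation of the R implementations.

Reads a JSON list of datasets (fields: x, y, u, v, g) and writes, per
dataset: Shapiro-Wilk W of x, pooled two-sample t and p, Mann-Whitney U of
x, Pearson r and p of (u, v), OLS slope of v on u with p, and the ANCOVA
interaction F and p for v ~ g + u + g:u via nested least squares.
"""
import json
import sys

import numpy as np
from scipy import stats


def ancova_interaction(v, u, g):
    n = len(v)
    inter = np.column_stack([np.ones(n), g, u, g * u])
    main = inter[:, :3]
    rss = lambda X: np.sum((v - X @ np.linalg.lstsq(X, v, rcond=None)[0]) ** 2)
    r1 = rss(inter)
    r0 = rss(main)
    f = (r0 - r1) / (r1 / (n - inter.shape[1]))
    p = stats.f.sf(f, 1, n - inter.shape[1])
    return f, p


def main(src, dst):
    with open(src) as fh:
        datasets = json.load(fh)
    out = []
    for d in datasets:
        x = np.asarray(d["x"], float)
        y = np.asarray(d["y"], float)
        u = np.asarray(d["u"], float)
        v = np.asarray(d["v"], float)
        g = np.asarray(d["g"], float)
        t, tp = stats.ttest_ind(x, y, equal_var=True)
        uu = stats.mannwhitneyu(x, y, alternative="two-sided").statistic
        r, rp = stats.pearsonr(u, v)
        lr = stats.linregress(u, v)
        f, fp = ancova_interaction(v, u, g)
        out.append({
            "sw_w_x": stats.shapiro(x).statistic,
            "t": t, "t_p": tp, "u_stat": uu,
            "r": r, "r_p": rp,
            "beta": lr.slope, "beta_p": lr.pvalue,
            "ancova_f": f, "ancova_p": fp,
        })
    with open(dst, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
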