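"""Bridge between AnnData .h5ad containers and the package's CSV layout.

Usage:
  python h5ad_io.py export <file.h5ad> <out_dir>   # h5ad -> csv triplet
  python h5ad_io.py import <csv_dir> <file.h5ad>   # csv triplet -> h5ad

Coordinates are taken from obsm['spatial'] (or the first obsm slot whose
name contains 'spatial'); labels, when present, from obs['label'] or
obs['domain'].
"""
import sys

import numpy as np
import pandas as pd


def export(path, out_dir):
    import anndata as ad

    a = ad.read_h5ad(path)
    X = a.X
    if hasattr(X, "toarray"):
        X = X.toarray()
    X = np.asarray(X)
    spots = [str(s) for s in a.obs_names]
    feats = [str(f) for f in a.var_names]
    key = "spatial"
    if key not in a.obsm:
        cand = [k for k in a.obsm.keys() if "spatial" in k.lower()]
        if not cand:
            raise SystemExit("no spatial slot in obsm")
        key = cand[0]
    coords = np.asarray(a.obsm[key])[:, :2]
    pd.DataFrame(X, index=spots, columns=feats).to_csv(
        f"{out_dir}/expression.csv"
    )
    pd.DataFrame(
        {"spot_id": spots, "x": coords[:, 0], "y": coords[:, 1]}
    ).to_csv(f"{out_dir}/coordinates.csv", index=False)
    for col in ("label", "domain"):
        if col in a.obs.columns:
            lab = pd.Categorical(a.obs[col]).codes + 1
            pd.DataFrame({"spot_id": spots, "label": lab}).to_csv(
                f"{out_dir}/labels.csv", index=False
            )
            break


def import_(csv_dir, path):
    import anndata as ad

    expr = pd.read_csv(f"{csv_dir}/expression.csv", index_col=0)
    coords = pd.read_csv(f"{csv_dir}/coordinates.csv")
    a = ad.AnnData(
        X=expr.to_numpy(dtype=float),
        obs=pd.DataFrame(index=expr.index.astype(str)),
        var=pd.DataFrame(index=expr.columns.astype(str)),
    )
    a.obsm["spatial"] = coords[["x", "y"]].to_numpy(dtype=float)
    try:
        lab = pd.read_csv(f"{csv_dir}/labels.csv")
        a.obs["label"] = lab["label"].to_numpy()
    except FileNotFoundError:
        pass
    a.write_h5ad(path)


if __name__ == "__main__":
    mode, src, dst = sys.argv[1:4]
    if mode == "export":
        export(src, dst)
    elif mode == "import":
        import_(src, dst)
    else:
        raise SystemExit(f"unknown mode {mode}")
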