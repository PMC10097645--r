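"""Shuttle between AnnData h5ad and MatrixMarket (genes x cells on disk).

Usage:
  python h5ad_bridge.py export <in.h5ad> <out.mtx> [layer]
  python h5ad_bridge.py import <in.mtx> <out.h5ad>
"""
import os
import sys

import anndata
import numpy as np
import pandas as pd
import scipy.io
import scipy.sparse


def do_export(h5ad_path, mtx_path, layer=None):
    ad = anndata.read_h5ad(h5ad_path)
    x = ad.layers[layer] if layer else ad.X
    x = scipy.sparse.csc_matrix(x)
    d = os.path.dirname(mtx_path) or "."
    scipy.io.mmwrite(mtx_path, x.T)  # genes x cells
    pd.Series(ad.var_names).to_csv(os.path.join(d, "genes.tsv"),
                                   sep="\t", index=False, header=False)
    pd.Series(ad.obs_names).to_csv(os.path.join(d, "barcodes.tsv"),
                                   sep="\t", index=False, header=False)


def do_import(mtx_path, h5ad_path):
    d = os.path.dirname(mtx_path) or "."
    x = scipy.io.mmread(mtx_path).T.tocsr()  # cells x genes
    genes = pd.read_csv(os.path.join(d, "genes.tsv"), sep="\t", header=None)[0]
    cells = pd.read_csv(os.path.join(d, "barcodes.tsv"), sep="\t", header=None)[0]
    obs_idx = pd.Index(cells.astype(str).to_numpy(), name=None)
    var_idx = pd.Index(genes.astype(str).to_numpy(), name=None)
    ad = anndata.AnnData(X=x,
                         obs=pd.DataFrame(index=obs_idx),
                         var=pd.DataFrame(index=var_idx))
    ad.write_h5ad(h5ad_path)


if __name__ == "__main__":
    cmd = sys.argv[1]
    if cmd == "export":
        do_export(sys.argv[2], sys.argv[3], sys.argv[4] if len(sys.argv) > 4 else None)
    elif cmd == "import":
        do_import(sys.argv[2], sys.argv[3])
    else:
        sys.exit("unknown command: " + cmd)
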