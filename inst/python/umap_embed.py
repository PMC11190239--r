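"""UMAP embedding worker: CSV in, CSV out.

Usage: python umap_embed.py IN OUT N_NEIGHBORS MIN_DIST N_COMPONENTS SEED
"""
import sys
import warnings

import numpy as np


def main() -> None:
    fin, fout = sys.argv[1], sys.argv[2]
    n_neighbors = int(sys.argv[3])
    min_dist = float(sys.argv[4])
    n_components = int(sys.argv[5])
    seed = int(sys.argv[6])

    with warnings.catch_warnings():
        warnings.simplefilter("ignore")
        import umap

        x = np.loadtxt(fin, delimiter=",", ndmin=2)
        emb = umap.UMAP(
            n_neighbors=n_neighbors,
            min_dist=min_dist,
            n_components=n_components,
            random_state=seed,
        ).fit_transform(x)
    np.savetxt(fout, emb, delimiter=",")


if __name__ == "__main__":
    main()
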