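"""Seeded 3D conformer embedding for trscreen.

Usage: python embed3d.py <in.sdf> <n_confs> <seed> <out.sdf>

Reads a multi-record V2000 SDF (heavy atoms, formal charges), adds
hydrogens, embeds up to n_confs distinct conformers per record with ETKDGv3
under a deterministic per-record seed, and writes one SDF record per
conformer titled "<id>|c<k>".  Heavy-atom order of the input is preserved
(added hydrogens are appended), so callers may map conformer atoms back to
the input graph positionally.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main(argv):
    inp, n_confs, seed, out = argv[0], int(argv[1]), int(argv[2]), argv[3]
    supplier = Chem.SDMolSupplier(inp, removeHs=False, sanitize=True)
    writer = Chem.SDWriter(out)
    for i, mol in enumerate(supplier):
        if mol is None:
            continue
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else f"mol{i + 1}"
        molh = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        # keep the derived per-record seed well inside 32-bit range
        params.randomSeed = (seed * 1000003 + i * 7919) % 2147483647
        params.pruneRmsThresh = 0.3
        cids = AllChem.EmbedMultipleConfs(molh, n_confs, params)
        if len(cids) == 0:
            # retry once with random coordinates (helps strained rings)
            params.useRandomCoords = True
            cids = AllChem.EmbedMultipleConfs(molh, n_confs, params)
        try:
            AllChem.MMFFOptimizeMoleculeConfs(molh, maxIters=200)
        except Exception:
            pass
        for k, cid in enumerate(cids):
            molh.SetProp("_Name", f"{name}|c{k + 1}")
            writer.write(molh, confId=cid)
    writer.close()


if __name__ == "__main__":
    main(sys.argv[1:])
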