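"""Deterministic single-conformer 3D embedding.

Reads SMILES (one per line, tab-separated id) from the file given as the
first argument, embeds one conformer per molecule with seeded ETKDG,
minimizes it with MMFF94 (UFF fallback), and writes a long-format CSV
(id,element,x,y,z) to the file given as the second argument. Molecules
that fail to embed are simply absent from the output.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def main(infile, outfile, seed=42, max_iters=500):
    rows = []
    with open(infile) as fh:
        for line in fh:
            line = line.rstrip("\n")
            if not line:
                continue
            smiles, _, mid = line.partition("\t")
            mol = Chem.MolFromSmiles(smiles)
            if mol is None:
                continue
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = int(seed)
            if AllChem.EmbedMolecule(mol, params) != 0:
                continue
            try:
                AllChem.MMFFOptimizeMolecule(mol, maxIters=int(max_iters))
            except Exception:
                try:
                    AllChem.UFFOptimizeMolecule(mol, maxIters=int(max_iters))
                except Exception:
                    pass
            conf = mol.GetConformer()
            for atom in mol.GetAtoms():
                pos = conf.GetAtomPosition(atom.GetIdx())
                rows.append((mid, atom.GetSymbol(), pos.x, pos.y, pos.z))
    with open(outfile, "w") as out:
        out.write("id,element,x,y,z\n")
        for mid, el, x, y, z in rows:
            out.write(f"{mid},{el},{x:.6f},{y:.6f},{z:.6f}\n")


if __name__ == "__main__":
    seed = sys.argv[3] if len(sys.argv) > 3 else 42
    main(sys.argv[1], sys.argv[2], seed)
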