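"""RDKit bridge used by the bondbreakr R package.

Reads a JSON request {"molecules": [{"identifier", "smiles", "embed", "seed"}]}
from argv[1], writes {"results": [...]} to argv[2].  One process call handles a
whole batch so the RDKit import cost is paid once.  All atom indices in the
output are 1-based to match R conventions.
"""

import json
import sys


def process(m, Chem, AllChem):
    mol = Chem.MolFromSmiles(m["smiles"])
    if mol is None:
        return {"error": "SMILES parse failure"}
    mol = Chem.AddHs(mol)
    out = {
        "elements": [a.GetSymbol() for a in mol.GetAtoms()],
        "bonds": [
            [
                b.GetBeginAtomIdx() + 1,
                b.GetEndAtomIdx() + 1,
                b.GetBondTypeAsDouble(),
                bool(b.GetIsAromatic()),
            ]
            for b in mol.GetBonds()
        ],
        "valences": [a.GetTotalValence() for a in mol.GetAtoms()],
        "formal_charges": [a.GetFormalCharge() for a in mol.GetAtoms()],
        "aromatic": [bool(a.GetIsAromatic()) for a in mol.GetAtoms()],
        "radical_electrons": [a.GetNumRadicalElectrons() for a in mol.GetAtoms()],
    }
    if m.get("embed"):
        params = AllChem.ETKDGv3()
        params.randomSeed = int(m.get("seed", 0))
        if AllChem.EmbedMolecule(mol, params) < 0:
            return {"error": "3D embedding failure"}
        conf = mol.GetConformer()
        out["coords"] = [
            [p.x, p.y, p.z]
            for p in (conf.GetAtomPosition(i) for i in range(mol.GetNumAtoms()))
        ]
    return out


def main():
    with open(sys.argv[1]) as fh:
        req = json.load(fh)
    from rdkit import Chem, RDLogger
    from rdkit.Chem import AllChem

    RDLogger.DisableLog("rdApp.*")
    results = [process(m, Chem, AllChem) for m in req["molecules"]]
    with open(sys.argv[2], "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main()
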