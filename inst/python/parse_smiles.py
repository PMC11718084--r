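"""Parse a JSON array of SMILES strings into heavy-atom graphs.

Usage: python parse_smiles.py INPUT.json  (writes a JSON array to stdout)

Each output element is {"atoms": [symbol, ...],
                        "bonds": [[u, v, order], ...]}   (0-based indices)
or {"error": message} for unparseable input. Hydrogens are removed;
aromaticity follows RDKit perception after sanitization.
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def parse_one(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"error": "RDKit sanitization/parse failure"}
    mol = Chem.RemoveHs(mol)
    idx = {}
    atoms = []
    for atom in mol.GetAtoms():
        if atom.GetSymbol() == "H":
            continue
        idx[atom.GetIdx()] = len(atoms)
        atoms.append(atom.GetSymbol())
    bonds = []
    for bond in mol.GetBonds():
        a, b = bond.GetBeginAtomIdx(), bond.GetEndAtomIdx()
        if a not in idx or b not in idx:
            continue
        bonds.append([idx[a], idx[b], bond.GetBondTypeAsDouble()])
    return {"atoms": atoms, "bonds": bonds}


def main():
    with open(sys.argv[1]) as fh:
        smiles = json.load(fh)
    json.dump([parse_one(s) for s in smiles], sys.stdout)


if __name__ == "__main__":
    main()
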