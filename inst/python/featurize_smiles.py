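"""Batched SMILES featurization.

Reads a JSON array of {"id": ..., "smiles": ...} records from the file given
as argv[1] and writes a JSON array of per-molecule graphs to argv[2]:
  {"id", "ok", "error"?, "n_nodes", "node_features" [[...]...],
   "edges" [[i, j]...] (0-based, each bond once), "edge_features" [[...]...]}

Node features (22): atom-type one-hot over (C, N, O, S, P, F, Cl, Br, I,
other); atomic mass / 100; total valence; in-ring; formal charge; radical
electrons; chirality one-hot (none, CW, CCW, other); degree; total H count;
aromaticity. Bond features (10): type one-hot (single, double, triple,
aromatic); in-ring; conjugated; stereo one-hot (none, Z, E, other).
Hydrogens are implicit: the graph covers heavy atoms only.
"""

import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

ELEMENTS = ["C", "N", "O", "S", "P", "F", "Cl", "Br", "I"]

CHIRAL = {
    Chem.ChiralType.CHI_UNSPECIFIED: 0,
    Chem.ChiralType.CHI_TETRAHEDRAL_CW: 1,
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW: 2,
}

BOND_TYPE = {
    Chem.BondType.SINGLE: 0,
    Chem.BondType.DOUBLE: 1,
    Chem.BondType.TRIPLE: 2,
    Chem.BondType.AROMATIC: 3,
}

STEREO = {
    Chem.BondStereo.STEREONONE: 0,
    Chem.BondStereo.STEREOZ: 1,
    Chem.BondStereo.STEREOE: 2,
}


def one_hot(index, size):
    v = [0.0] * size
    v[index] = 1.0
    return v


def atom_features(atom):
    sym = atom.GetSymbol()
    type_idx = ELEMENTS.index(sym) if sym in ELEMENTS else len(ELEMENTS)
    feats = one_hot(type_idx, len(ELEMENTS) + 1)
    feats.append(atom.GetMass() / 100.0)
    feats.append(float(atom.GetTotalValence()))
    feats.append(1.0 if atom.IsInRing() else 0.0)
    feats.append(float(atom.GetFormalCharge()))
    feats.append(float(atom.GetNumRadicalElectrons()))
    feats.extend(one_hot(CHIRAL.get(atom.GetChiralTag(), 3), 4))
    feats.append(float(atom.GetDegree()))
    feats.append(float(atom.GetTotalNumHs()))
    feats.append(1.0 if atom.GetIsAromatic() else 0.0)
    return feats


def bond_features(bond):
    feats = one_hot(BOND_TYPE.get(bond.GetBondType(), 0), 4)
    feats.append(1.0 if bond.IsInRing() else 0.0)
    feats.append(1.0 if bond.GetIsConjugated() else 0.0)
    feats.extend(one_hot(STEREO.get(bond.GetStereo(), 3), 4))
    return feats


def featurize(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    nodes = [atom_features(a) for a in mol.GetAtoms()]
    edges, efeats = [], []
    for bond in mol.GetBonds():
        edges.append([bond.GetBeginAtomIdx(), bond.GetEndAtomIdx()])
        efeats.append(bond_features(bond))
    return {
        "n_nodes": len(nodes),
        "node_features": nodes,
        "edges": edges,
        "edge_features": efeats,
    }


def main():
    with open(sys.argv[1]) as fh:
        records = json.load(fh)
    out = []
    for rec in records:
        graph = featurize(rec["smiles"])
        if graph is None:
            out.append({"id": rec["id"], "ok": False,
                        "error": "unparseable SMILES: %s" % rec["smiles"]})
        else:
            graph.update({"id": rec["id"], "ok": True})
            out.append(graph)
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
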