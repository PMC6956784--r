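"""Ligand descriptor backend.

Reads a molecule file (SMILES / SDF V2000 / MOL2), computes the 11-descriptor
set plus the engineered rotatable-bond fraction and the 166-bit MACCS keys,
and writes one CSV row per input record.

Conventions (frozen by the R package's tests):
  * nAtom counts all atoms including implicit hydrogens
  * nBond counts heavy-atom--heavy-atom bonds only
  * rotatable bond: non-ring single bond between two heavy atoms that each
    have >= 2 heavy neighbours, excluding amide C-N bonds
  * HybRatio = (sp3 C) / (sp2 C + sp3 C), 0 when there are no sp2/sp3 carbons
  * VABC: Zhao-Abraham-Zissimos additive van der Waals volume
  * XLogP column carries Wildman-Crippen logP (see package docs)
"""

import argparse
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, MACCSkeys, rdMolDescriptors
from rdkit.Chem.rdchem import HybridizationType

RDLogger.DisableLog("rdApp.*")

# Zhao, Abraham & Zissimos (2003) atomic volume contributions, A^3
VABC_ATOM = {
    "H": 7.24, "C": 20.58, "N": 15.60, "O": 14.71, "F": 13.31, "Cl": 22.45,
    "Br": 26.52, "I": 32.52, "P": 24.43, "S": 24.43, "As": 26.52, "B": 40.48,
    "Si": 38.79, "Se": 28.73, "Te": 36.62,
}

AMIDE = Chem.MolFromSmarts("[NX3][CX3]=[OX1]")

FIELDS = [
    "ligand_id", "status", "message", "MW", "VABC", "nAtom", "nBond",
    "nRotBond", "nAromBond", "nHBDon", "nHBAcc", "TPSA", "XLogP", "HybRatio",
    "nRotB_nB", "maccs", "canonical_smiles",
]


def n_rotatable(mol):
    amide_bonds = set()
    for match in mol.GetSubstructMatches(AMIDE):
        amide_bonds.add(frozenset(match[:2]))
    n = 0
    for b in mol.GetBonds():
        if b.GetBondType() != Chem.BondType.SINGLE or b.IsInRing():
            continue
        a1, a2 = b.GetBeginAtom(), b.GetEndAtom()
        if a1.GetDegree() < 2 or a2.GetDegree() < 2:
            continue
        if frozenset((a1.GetIdx(), a2.GetIdx())) in amide_bonds:
            continue
        n += 1
    return n


def vabc(mol):
    molh = Chem.AddHs(mol)
    total = 0.0
    for atom in molh.GetAtoms():
        sym = atom.GetSymbol()
        if sym not in VABC_ATOM:
            raise ValueError("no VABC contribution for element '%s'" % sym)
        total += VABC_ATOM[sym]
    n_bonds = molh.GetNumBonds()
    ri = mol.GetRingInfo()
    n_arom = n_nonarom = 0
    for ring in ri.BondRings():
        if all(mol.GetBondWithIdx(i).GetIsAromatic() for i in ring):
            n_arom += 1
        else:
            n_nonarom += 1
    return total - 5.92 * n_bonds - 14.7 * n_arom - 3.8 * n_nonarom


def hyb_ratio(mol):
    sp3 = sp2 = 0
    for atom in mol.GetAtoms():
        if atom.GetSymbol() != "C":
            continue
        h = atom.GetHybridization()
        if h == HybridizationType.SP3:
            sp3 += 1
        elif h == HybridizationType.SP2:
            sp2 += 1
    return 0.0 if sp3 + sp2 == 0 else sp3 / (sp3 + sp2)


def describe(mol):
    n_bond = mol.GetNumBonds()
    n_rot = n_rotatable(mol)
    bits = [b for b in MACCSkeys.GenMACCSKeys(mol).GetOnBits() if b >= 1]
    return {
        "MW": round(Descriptors.MolWt(mol), 6),
        "VABC": round(vabc(mol), 6),
        "nAtom": Chem.AddHs(mol).GetNumAtoms(),
        "nBond": n_bond,
        "nRotBond": n_rot,
        "nAromBond": sum(1 for b in mol.GetBonds() if b.GetIsAromatic()),
        "nHBDon": rdMolDescriptors.CalcNumHBD(mol),
        "nHBAcc": rdMolDescriptors.CalcNumHBA(mol),
        "TPSA": round(rdMolDescriptors.CalcTPSA(mol), 6),
        "XLogP": round(Crippen.MolLogP(mol), 6),
        "HybRatio": round(hyb_ratio(mol), 6),
        "nRotB_nB": round(n_rot / n_bond, 6) if n_bond > 0 else "",
        "maccs": ";".join(str(b) for b in bits),
        "canonical_smiles": Chem.MolToSmiles(mol),
    }


def iter_smiles(path):
    with open(path) as fh:
        for i, line in enumerate(fh):
            line = line.strip()
            if not line or line.startswith("#"):
                continue
            parts = line.split(None, 1)
            lid = parts[1].strip() if len(parts) > 1 else "mol%d" % (i + 1)
            yield lid, Chem.MolFromSmiles(parts[0])


def iter_sdf(path):
    supplier = Chem.SDMolSupplier(path, sanitize=True, removeHs=True)
    for i, mol in enumerate(supplier):
        if mol is None:
            yield "record%d" % (i + 1), None
        else:
            name = mol.GetProp("_Name") if mol.HasProp("_Name") else ""
            yield name.strip() or "record%d" % (i + 1), mol


def iter_mol2(path):
    with open(path) as fh:
        text = fh.read()
    blocks = ["@<TRIPOS>MOLECULE" + b for b in text.split("@<TRIPOS>MOLECULE")[1:]]
    for i, block in enumerate(blocks):
        name = block.splitlines()[1].strip() if len(block.splitlines()) > 1 else ""
        mol = Chem.MolFromMol2Block(block, sanitize=True, removeHs=True)
        yield name or "record%d" % (i + 1), mol


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--infile", required=True)
    ap.add_argument("--format", choices=["smiles", "sdf", "mol2"], required=True)
    ap.add_argument("--out", default="-")
    args = ap.parse_args()

    readers = {"smiles": iter_smiles, "sdf": iter_sdf, "mol2": iter_mol2}
    out = sys.stdout if args.out == "-" else open(args.out, "w", newline="")
    writer = csv.DictWriter(out, fieldnames=FIELDS)
    writer.writeheader()
    for lid, mol in readers[args.format](args.infile):
        row = {k: "" for k in FIELDS}
        row["ligand_id"] = lid
        if mol is None or mol.GetNumHeavyAtoms() == 0:
            row["status"] = "error"
            row["message"] = "unparseable structure or no heavy atoms"
        else:
            try:
                row.update(describe(mol))
                row["status"] = "ok"
            except Exception as exc:  # e.g. exotic element without VABC value
                row["status"] = "error"
                row["message"] = str(exc)
        writer.writerow(row)
    if out is not sys.stdout:
        out.close()


if __name__ == "__main__":
    main()
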