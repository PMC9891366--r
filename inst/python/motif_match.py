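"""SMARTS motif matching helper.

Reads a JSON job from stdin:

    {"molecules": [{"id": str,
                    "smiles": str                       # either this ...
                    } | {
                    "id": str,                          # ... or coordinates
                    "elements": [str, ...],
                    "coords": [[x, y, z], ...],
                    "bonds": [[i, j], ...],             # 0-based, optional
                    "charge": int}],
     "patterns": [{"name": str, "smarts": str, "add_h": bool}]}

Writes JSON to stdout: per molecule, atom annotations (element, aromatic,
n_h), bond annotations (i, j, order, aromatic), all unique substructure
matches per pattern (0-based atom indices, optionally grown to include the
hydrogens bonded to matched heavy atoms), and any perception warnings.
Molecules built from coordinates keep the input atom order, so match
indices refer directly to the caller's atoms.
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger
from rdkit.Chem import rdDetermineBonds

RDLogger.DisableLog("rdApp.*")


def mol_from_coords(spec, warnings):
    mol = Chem.RWMol()
    for el in spec["elements"]:
        a = Chem.Atom(el)
        a.SetNoImplicit(True)
        mol.AddAtom(a)
    conf = Chem.Conformer(mol.GetNumAtoms())
    for i, (x, y, z) in enumerate(spec["coords"]):
        conf.SetAtomPosition(i, (float(x), float(y), float(z)))
    mol.AddConformer(conf)
    try:
        m = Chem.Mol(mol)
        rdDetermineBonds.DetermineBonds(m, charge=int(spec.get("charge", 0)))
        Chem.SanitizeMol(m)
        return m
    except Exception as exc:  # fall back to supplied single bonds
        warnings.append("bond-order perception failed (%s); using single "
                        "bonds from the supplied connectivity" % exc)
    for i, j in spec.get("bonds", []):
        mol.AddBond(int(i), int(j), Chem.BondType.SINGLE)
    m = Chem.Mol(mol)
    try:
        Chem.SanitizeMol(
            m,
            Chem.SanitizeFlags.SANITIZE_ALL
            ^ Chem.SanitizeFlags.SANITIZE_PROPERTIES,
        )
    except Exception as exc:
        warnings.append("sanitization incomplete: %s" % exc)
    return m


def mol_from_smiles(spec, warnings):
    m = Chem.MolFromSmiles(spec["smiles"])
    if m is None:
        raise ValueError("unparsable SMILES: %r" % spec["smiles"])
    return m


def describe(mol):
    atoms = [
        {
            "element": a.GetSymbol(),
            "aromatic": a.GetIsAromatic(),
            "n_h": a.GetTotalNumHs(includeNeighbors=True),
        }
        for a in mol.GetAtoms()
    ]
    bonds = [
        {
            "i": b.GetBeginAtomIdx(),
            "j": b.GetEndAtomIdx(),
            "order": b.GetBondTypeAsDouble(),
            "aromatic": b.GetIsAromatic(),
        }
        for b in mol.GetBonds()
    ]
    ri = mol.GetRingInfo()
    rings = [list(r) for r in ri.AtomRings()]
    return atoms, bonds, rings


def grow_hydrogens(mol, match):
    out = set(match)
    for idx in match:
        for nb in mol.GetAtomWithIdx(idx).GetNeighbors():
            if nb.GetSymbol() == "H":
                out.add(nb.GetIdx())
    return tuple(sorted(out))


def main():
    job = json.load(sys.stdin)
    patterns = []
    for p in job.get("patterns", []):
        q = Chem.MolFromSmarts(p["smarts"])
        if q is None:
            raise ValueError("unparsable SMARTS for pattern %r: %r"
                             % (p["name"], p["smarts"]))
        patterns.append((p["name"], q, bool(p.get("add_h", True))))
    result = []
    for spec in job.get("molecules", []):
        warnings = []
        try:
            if "smiles" in spec:
                mol = mol_from_smiles(spec, warnings)
            else:
                mol = mol_from_coords(spec, warnings)
            atoms, bonds, rings = describe(mol)
            matches = []
            for name, q, add_h in patterns:
                seen = set()
                for m in mol.GetSubstructMatches(q, uniquify=True):
                    idx = grow_hydrogens(mol, m) if add_h else tuple(sorted(m))
                    if idx in seen:
                        continue
                    seen.add(idx)
                    matches.append({"pattern": name, "atoms": list(idx)})
            result.append({
                "id": spec["id"], "ok": True, "atoms": atoms, "bonds": bonds,
                "rings": rings, "matches": matches, "warnings": warnings,
            })
        except Exception as exc:
            result.append({"id": spec["id"], "ok": False, "error": str(exc)})
    json.dump({"molecules": result}, sys.stdout)


if __name__ == "__main__":
    main()
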