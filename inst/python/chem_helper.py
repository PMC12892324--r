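"""RDKit backend for the votedock R package.

Batched, file-based protocol: every subcommand reads a CSV with columns
(id, smiles) and writes a CSV. Called from R via subprocess; keep stdlib-only
besides RDKit.

Subcommands:
  standardize in.csv out.csv      -> id, smiles_std, reject_reason, log
  fingerprint in.csv out.csv --nbits N -> id, bits (bit string, empty on error)
  logp in.csv out.csv             -> id, logp (empty on error)
  sdf_to_csv in.sdf out.csv       -> id, smiles (raw, from SDF records)
"""

import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen, Descriptors, rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")

# Organic-chemistry allowlist; anything else (Na, Zn, Sn, ...) marks the
# compound as metal-containing once counterion fragments are stripped.
ALLOWED = {"H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I"}

NEUTRALIZE_PATTERN = Chem.MolFromSmarts(
    "[+1!h0!$([*]~[-1,-2,-3,-4]),-1!$([*]~[+1,+2,+3,+4])]"
)


def largest_fragment(mol, log):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    if len(frags) == 1:
        return mol
    # heavy-atom count, ties by molecular weight, then canonical string
    def key(m):
        return (m.GetNumHeavyAtoms(), Descriptors.MolWt(m), Chem.MolToSmiles(m))

    frags = sorted(frags, key=key, reverse=True)
    log.append("salt_strip")
    return frags[0]


def neutralize(mol, log):
    matches = mol.GetSubstructMatches(NEUTRALIZE_PATTERN)
    if not matches:
        return mol
    for (idx,) in matches:
        atom = mol.GetAtomWithIdx(idx)
        charge = atom.GetFormalCharge()
        hcount = atom.GetTotalNumHs()
        atom.SetFormalCharge(0)
        atom.SetNumExplicitHs(hcount - charge)
        atom.UpdatePropertyCache()
    log.append("neutralize")
    return mol


def standardize_one(smiles):
    """Fixed rule order: parse -> salt strip -> inorganic/metal filter ->
    neutralize -> drop stereo -> canonicalize."""
    log = []
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return "", "parse_error", "parse_failed"
    log.append("parse")
    mol = largest_fragment(mol, log)
    symbols = {a.GetSymbol() for a in mol.GetAtoms()}
    if "C" not in symbols:
        return "", "inorganic", ";".join(log + ["reject_inorganic"])
    if symbols - ALLOWED:
        return "", "metal", ";".join(log + ["reject_metal"])
    mol = neutralize(mol, log)
    if any(a.GetChiralTag() != Chem.ChiralType.CHI_UNSPECIFIED
           for a in mol.GetAtoms()) or \
       any(b.GetStereo() != Chem.BondStereo.STEREONONE for b in mol.GetBonds()):
        log.append("remove_stereo")
    Chem.RemoveStereochemistry(mol)
    try:
        smi = Chem.MolToSmiles(mol)
        # re-parse to guarantee a sanitized canonical form
        mol2 = Chem.MolFromSmiles(smi)
        if mol2 is None:
            return "", "parse_error", ";".join(log + ["canonicalize_failed"])
        smi = Chem.MolToSmiles(mol2)
    except Exception:
        return "", "parse_error", ";".join(log + ["canonicalize_failed"])
    log.append("canonicalize")
    return smi, "none", ";".join(log)


def read_rows(path):
    with open(path, newline="") as fh:
        return list(csv.DictReader(fh))


def write_rows(path, header, rows):
    with open(path, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(header)
        w.writerows(rows)


def main(argv):
    cmd, inp, out = argv[0], argv[1], argv[2]
    opts = dict(zip(argv[3::2], argv[4::2]))
    if cmd == "standardize":
        rows = [(r["id"], *standardize_one(r["smiles"])) for r in read_rows(inp)]
        write_rows(out, ["id", "smiles_std", "reject_reason", "log"], rows)
    elif cmd == "fingerprint":
        nbits = int(opts.get("--nbits", 2048))
        gen = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=nbits)
        rows = []
        for r in read_rows(inp):
            mol = Chem.MolFromSmiles(r["smiles"])
            bits = gen.GetFingerprint(mol).ToBitString() if mol else ""
            rows.append((r["id"], bits))
        write_rows(out, ["id", "bits"], rows)
    elif cmd == "logp":
        rows = []
        for r in read_rows(inp):
            mol = Chem.MolFromSmiles(r["smiles"])
            rows.append((r["id"], Crippen.MolLogP(mol) if mol else ""))
        write_rows(out, ["id", "logp"], rows)
    elif cmd == "sdf_to_csv":
        rows = []
        supplier = Chem.SDMolSupplier(inp, sanitize=True)
        for i, mol in enumerate(supplier):
            if mol is None:
                rows.append((f"sdf_{i + 1}", ""))
                continue
            mid = mol.GetProp("_Name") if mol.HasProp("_Name") and \
                mol.GetProp("_Name").strip() else f"sdf_{i + 1}"
            rows.append((mid, Chem.MolToSmiles(mol)))
        write_rows(out, ["id", "smiles"], rows)
    else:
        raise SystemExit(f"unknown subcommand: {cmd}")


if __name__ == "__main__":
    main(sys.argv[1:])
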