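"""RDKit fingerprint helper.

Usage: python fingerprints.py <infile> <outfile> <fp_type> <n_bits>

<infile>: one structure string (SMILES or InChI, auto-detected) per line.
<outfile>: JSON {"rdkit_version": ..., "fingerprints": [[active 0-based bit
positions] or ["ERROR"] per input line]}.
"""
import json
import sys

from rdkit import Chem, rdBase
from rdkit.Chem import AllChem, RDKFingerprint
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def parse(structure):
    structure = structure.strip()
    if structure.startswith("InChI="):
        return Chem.MolFromInchi(structure)
    return Chem.MolFromSmiles(structure)


def main():
    infile, outfile, fp_type, n_bits = sys.argv[1:5]
    n_bits = int(n_bits)
    out = []
    with open(infile) as fh:
        for line in fh:
            if not line.strip():
                out.append(["ERROR"])
                continue
            mol = parse(line)
            if mol is None:
                out.append(["ERROR"])
                continue
            if fp_type == "daylight":
                fp = RDKFingerprint(mol, fpSize=n_bits)
            elif fp_type in ("morgan2", "morgan3"):
                radius = 2 if fp_type == "morgan2" else 3
                fp = AllChem.GetMorganFingerprintAsBitVect(
                    mol, radius, nBits=n_bits)
            else:
                raise SystemExit(f"unknown fp_type {fp_type}")
            out.append(sorted(fp.GetOnBits()))
    with open(outfile, "w") as fh:
        json.dump({"rdkit_version": rdBase.rdkitVersion,
                   "fingerprints": out}, fh)


if __name__ == "__main__":
    main()
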