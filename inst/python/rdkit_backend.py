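"""Chemistry backend: Morgan fingerprints and RDKit molecular descriptors.

Called by the R package as
    python rdkit_backend.py fp  {bit|count} RADIUS NBITS in.csv out.csv
    python rdkit_backend.py desc                       in.csv out.csv
where in.csv has columns id,smiles. Unparseable SMILES abort with the
offending ids on stderr.
"""
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def read_molecules(path):
    with open(path, newline="") as fh:
        rows = list(csv.DictReader(fh))
    mols, bad = [], []
    for row in rows:
        mol = Chem.MolFromSmiles(row["smiles"])
        if mol is None:
            bad.append(row["id"])
        else:
            mols.append((row["id"], mol))
    if bad:
        sys.stderr.write("unparseable SMILES for molecule id(s): %s\n" % ", ".join(bad))
        sys.exit(2)
    return mols


def run_fp(kind, radius, nbits, infile, outfile):
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=nbits)
    mols = read_molecules(infile)
    with open(outfile, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["id"] + ["bit%d" % i for i in range(nbits)])
        for mid, mol in mols:
            if kind == "bit":
                fp = gen.GetFingerprint(mol)
                row = [int(fp.GetBit(i)) for i in range(nbits)]
            else:
                fp = gen.GetCountFingerprint(mol)
                row = [fp[i] for i in range(nbits)]
            w.writerow([mid] + row)


def run_desc(infile, outfile):
    mols = read_molecules(infile)
    names = [n for n, _ in Descriptors.descList]
    with open(outfile, "w", newline="") as fh:
        w = csv.writer(fh)
        w.writerow(["id"] + names)
        for mid, mol in mols:
            vals = Descriptors.CalcMolDescriptors(mol)
            w.writerow([mid] + [vals.get(n, "") for n in names])


def main(argv):
    mode = argv[1]
    if mode == "fp":
        run_fp(argv[2], int(argv[3]), int(argv[4]), argv[5], argv[6])
    elif mode == "desc":
        run_desc(argv[2], argv[3])
    else:
        sys.stderr.write("unknown mode: %s\n" % mode)
        sys.exit(1)


if __name__ == "__main__":
    main(sys.argv)
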