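"""Batch property scoring: validity (sanitization), QED, SA score.

Usage: python props.py input.smi output.tsv
Input: one SMILES per line. Output: TSV with header valid/qed/sa.
"""
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import QED, RDConfig

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")


def main(inp, out):
    with open(inp) as fh, open(out, "w") as oh:
        oh.write("valid\tqed\tsa\n")
        for line in fh:
            smi = line.strip()
            mol = Chem.MolFromSmiles(smi) if smi else None
            if mol is None:
                oh.write("0\tNA\tNA\n")
            else:
                oh.write("1\t%.6f\t%.6f\n"
                         % (QED.qed(mol), sascorer.calculateScore(mol)))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
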