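"""Deterministic 3-D embedding of a mol block (ETKDG, fixed random seed).

Reads one V2000 mol block on stdin, writes the embedded mol block on stdout.
Atom order is preserved.  Usage: python embed_conformer.py [seed]
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

block = sys.stdin.read()
mol = Chem.MolFromMolBlock(block, removeHs=False, sanitize=True)
if mol is None:
    sys.stderr.write("could not sanitize mol block\n")
    sys.exit(2)
params = AllChem.ETKDGv3()
params.randomSeed = int(sys.argv[1]) if len(sys.argv) > 1 else 42
params.useRandomCoords = False
cid = AllChem.EmbedMolecule(mol, params)
if cid < 0:
    sys.stderr.write("embedding failed\n")
    sys.exit(3)
sys.stdout.write(Chem.MolToMolBlock(mol, confId=cid))
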