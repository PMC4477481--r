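#!/usr/bin/env python
"""Reference DSSP assignments via mdtraj, for cross-checking.

Usage: python dssp_oracle.py file1.pdb [file2.pdb ...]
Prints one line per model: <file>\t<model>\t<8-state string> (loop = C).
"""
import sys

import mdtraj as md

for path in sys.argv[1:]:
    traj = md.load(path)
    ss = md.compute_dssp(traj, simplified=False)
    for m in range(ss.shape[0]):
        states = "".join(c if c.strip() else "C" for c in ss[m])
        sys.stdout.write(f"{path}\t{m + 1}\t{states}\n")
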