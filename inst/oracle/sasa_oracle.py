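#!/usr/bin/env python
"""Reference per-residue SASA via mdtraj's Shrake-Rupley, for cross-checking.

Usage: python sasa_oracle.py file.pdb [n_sphere_points]
Prints one line per residue of model 1: <res_index>\t<sasa_A2>.
"""
import sys

import mdtraj as md

path = sys.argv[1]
n_points = int(sys.argv[2]) if len(sys.argv) > 2 else 960
traj = md.load(path)[0]
sasa = md.shrake_rupley(traj, probe_radius=0.14, n_sphere_points=n_points,
                        mode="residue")
for i, v in enumerate(sasa[0]):
    sys.stdout.write(f"{i + 1}\t{v * 100.0}\n")  # nm^2 -> A^2
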