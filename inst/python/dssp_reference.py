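"""Reference DSSP assignment via mdtraj (DSSP-2.2.0-based implementation).

Usage: python dssp_reference.py structure.pdb [more.pdb ...]
Prints one line per frame per file: <file>\t<frame>\t<codes>, with loop
residues printed as 'C'.
"""

import sys

import mdtraj as md


def main(paths):
    for path in paths:
        traj = md.load(path)
        codes = md.compute_dssp(traj, simplified=False)
        for k in range(codes.shape[0]):
            line = "".join(codes[k]).replace(" ", "C")
            sys.stdout.write(f"{path}\t{k}\t{line}\n")


if __name__ == "__main__":
    main(sys.argv[1:])
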