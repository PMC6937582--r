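# Deposited coordinate files (not redistributed)

The acceptance tests that analyse the real crystal structures expect two
files in this directory, downloadable from the Protein Data Bank:

* `6hby.pdb` — HLA-DR1 in complex with the 5T4(111–130) 20-mer peptide
  (two complex copies in the asymmetric unit).
* `4cnm.pdb` — the native 5T4 whole-protein antigen (loop residues
  125–128 are used for the superposition check).

For example:

```sh
curl -o 6hby.pdb https://files.rcsb.org/download/6HBY.pdb
curl -o 4cnm.pdb https://files.rcsb.org/download/4CNM.pdb
```

Without these files the corresponding three acceptance tests fail on
their file-presence assertion; every other test runs on synthetic
fixtures generated in code.
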