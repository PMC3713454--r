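# Reference inputs (not shipped)

The quantitative crystal-structure and sequence checks need reference data that
cannot be redistributed with the package. To run them, place here:

- `3BE1.pdb`  - Her2 ectodomain monomer
- `1IVO.pdb`, `1MOX.pdb` - 2-ligand EGFR ectodomain dimers
- `3LTF.pdb`  - 2-ligand dEGFR ectodomain dimer
- `3I2T.pdb`  - ligand-free dEGFR ectodomain dimer (or another ligand-free entry)
- `ectodomains.fasta` - mature ectodomain sequences named EGFR, HER2, HER3
  (UniProt P00533 residues 25-644, P04626 23-652, P21860 20-643)

All other functionality, tests, and the acceptance script run entirely on
synthetic structures and need nothing here.
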