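Drop the real chitinase-ortholog inputs here to enable the full
reproduction test (tests/testthat/test-acceptance.R, last criterion):

  chiJ_protein.fasta  - aligned ChiJ ortholog protein sequences (FASTA)
  chiJ_codon.fasta    - the matching in-frame nucleotide alignment
  chiJ.nwk            - optional Newick tree (otherwise BIONJ is built)

The reference sequence (used for residue numbering) is detected as the
first identifier containing "Mg1".  These files are not distributed
with the package; they derive from public GenBank records.
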