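# Synthetic example cloning vector (ligation-independent cloning style).
#
# This is NOT a real vector: the backbone is a randomly generated stand-in
# carrying a promoter/RBS/tag/terminator layout so that the schema and the
# coordinate arithmetic can be demonstrated and tested offline. Replace it
# with your own vector definitions for real cloning work.
#
# Schema (one entry per vector under 'vectors:'):
#   name             unique vector name
#   overhang_fw      sequence: forward-primer overhang (copies the backbone
#                    immediately 5' of the placeholder); frame_offset: reading
#                    frame of the insert's first codon relative to the
#                    overhang 3' end (0 = insert starts a codon)
#   overhang_rv      sequence: reverse-primer overhang (reverse complement of
#                    the backbone immediately 3' of the placeholder)
#   tag_protein      N-terminal tag fused to the insert (one-letter codes)
#   cleavage_offset  tag residues retained on the insert after protease
#                    cleavage (omit when the vector has no protease site)
#   c_term_tag       optional C-terminal tag
#   backbone         full vector sequence containing the placeholder
#   placeholder      start/end (1-based inclusive) of the span the insert
#                    replaces
#   features         annotated backbone features (name, start, end, type)
vectors:
  - name: synthLIC-His6-TEV
    overhang_fw:
      sequence: CTGTATTTTCAGGGT
      frame_offset: 0
    overhang_rv:
      sequence: CTTTCGTTTTATTTG
      frame_offset: 0
    tag_protein: MHHHHHHENLYFQG
    cleavage_offset: 1
    features:
      - {name: promoter, start: 181, end: 215, type: regulatory}
      - {name: RBS, start: 216, end: 229, type: regulatory}
      - {name: His6-TEV tag, start: 230, end: 271, type: CDS}
      - {name: terminator, start: 292, end: 341, type: regulatory}
    placeholder: {start: 272, end: 291}
    backbone: >-
      TTATGTCACTTAATACGTGACTGATCCGTCATTTCTTCAGACCTAAGTGGGTGGGGGATCTACCCAGGCA
      CATACCTGTGAGGTAATTCAGATACGTACGACTAACGGCGACCGAGTCACTACCTGCGAGATTGGTTACT
      CGTTTGTGTTTCCTATCGTCCTCATCCTGAAAAGCCAGCATTGACAATTAATCATCGGCTCGTATAATGT
      GTGGAAAGGAGATATACATATGCACCACCACCATCATCATGAAAATCTGTATTTTCAGGGTTGCGCTCTG
      GAGTTAATATACAAATAAAACGAAAGGCTCAGTCGAAAGACTGGGCCTTTCGTTTTATCTGCCCAGATCG
      TAATTCTCATTCAGAACGGGATTTACTCGGACCGGACAGGACCATCCCGGCCAGTAGGGCCCCTACCTAA
      ACTAATTCTGGGTCTTTTACTCTTTACCAAAGGAGAGCTGTATTCCACGCTAATCTCACAATTAGTAATC
      GGTTCTTCTGGAATCTCCTGTGAGAGTACGAGATCGCCGGGTTCCGGCGCTTACGGCGTTGGCGAAAGAT
      T

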