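# Example mtphylo run configuration (synthetic-data mode).
#
# For file mode, replace the `synth` block with:
#   files:
#     dloop: path/to/dloop.fasta
#     cytb: path/to/cytb.fasta
#     population_map: path/to/population_map.tsv
#   ref_id: REF            # row used for reference numbering
#   ref_start_dloop: 15455 # reference position of D-loop column 1
synth:
  seed: 1
outgroup: Warthog
bootstrap:
  B: 1000
  seed: 1
clades: [European, Asian]
# Uncomment and point at a rate table (see substitution_rates.tsv bundled
# next to this file) to enable the divergence-dating report:
# rates: substitution_rates.tsv
# Control-region domain boundaries (reference coordinates) are required
# configuration for dating: there is no universally agreed ETAS/central
# split, so the user must state one.
etas_range: [15455, 15750]
central_range: [15751, 16067]
out_dir: mtphylo_out
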