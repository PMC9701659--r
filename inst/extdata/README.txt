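compounds.tsv  - compound reference (name, formula, KEGG ID) transcribed from
                 the printed annotation tables of the source study.
                 Monoisotopic masses are recomputed from the formulas at load.
pathways.gmt   - pathway membership sets (GMT) built from the same printed
                 tables. Memberships are the compounds those tables list, not
                 full KEGG snapshots, so pathway sizes are smaller than the
                 live database's.
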