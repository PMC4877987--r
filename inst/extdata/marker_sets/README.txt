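Placeholder (synthetic) marker identifier lists.

escg107.synthetic_ids.txt : 107 IDs standing in for the essential
  single-copy genes conserved in >95% of bacterial genomes.
cog35.synthetic_ids.txt   : 35 IDs standing in for the conserved
  single-copy COG cross-check set.

Only the set sizes matter to the completeness/redundancy arithmetic.
Replace with real accession lists (e.g. from the marker HMM collection you
search with) via marker_set("/path/to/ids.txt") for production use.
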