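# Packaged fixtures

- `metazoa_demo.nwk` — schematic rooted species tree (synthetic): one
  sponge, one cnidarian and four bilaterians with labelled internal nodes
  (Metazoa, Eumetazoa, Bilateria, Protostomia, Deuterostomia). It is a
  demonstration topology, not an inferred phylogeny.
- `repertoire_demo.tsv` — species x family gene counts for the 17
  DNA-methylation-machinery and NuRD families. The *Platynereis
  dumerilii* row is the published repertoire (single copy for 16
  families, four Chd3/4/5 members); the other rows are synthetic,
  chosen only to exercise presence/absence patterns (e.g. losses in the
  fly, duplications in vertebrates).
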