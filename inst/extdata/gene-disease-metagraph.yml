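# Gene-disease heterogeneous network schema: 18 metanodes, 19 undirected
# metaedges. Metanode abbreviations (uppercase tokens) and metaedge kind
# abbreviations (lowercase letters) compose metapath names, e.g. GeTlD.
metanodes:
  - {identifier: Disease, abbreviation: D}
  - {identifier: Gene, abbreviation: G}
  - {identifier: Tissue, abbreviation: T}
  - {identifier: Pathophysiology, abbreviation: P}
  - {identifier: Positional, abbreviation: Po}
  - {identifier: Perturbation, abbreviation: Pb}
  - {identifier: BioCarta, abbreviation: Bc}
  - {identifier: KEGG, abbreviation: Kg}
  - {identifier: Reactome, abbreviation: Rt}
  - {identifier: miRNA Target, abbreviation: Mr}
  - {identifier: TF Target, abbreviation: Tf}
  - {identifier: Cancer Hood, abbreviation: Cn}
  - {identifier: Cancer Module, abbreviation: Cm}
  - {identifier: GO Process, abbreviation: Gp}
  - {identifier: GO Component, abbreviation: Gc}
  - {identifier: GO Function, abbreviation: Gf}
  - {identifier: Oncogenic, abbreviation: Oc}
  - {identifier: Immunologic, abbreviation: Im}
metaedges:
  - {source: Disease, target: Gene, kind: association, abbreviation: a, direction: undirected}
  - {source: Disease, target: Pathophysiology, kind: membership, abbreviation: m, direction: undirected}
  - {source: Disease, target: Tissue, kind: localization, abbreviation: l, direction: undirected}
  - {source: Gene, target: Tissue, kind: expression, abbreviation: e, direction: undirected}
  - {source: Gene, target: Gene, kind: interaction, abbreviation: i, direction: undirected}
  - {source: Gene, target: Positional, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: Perturbation, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: BioCarta, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: KEGG, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: Reactome, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: miRNA Target, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: TF Target, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: Cancer Hood, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: Cancer Module, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: GO Process, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: GO Component, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: GO Function, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: Oncogenic, kind: membership, abbreviation: m, direction: undirected}
  - {source: Gene, target: Immunologic, kind: membership, abbreviation: m, direction: undirected}
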