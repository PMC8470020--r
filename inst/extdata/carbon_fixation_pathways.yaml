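# Essential-gene sets for the seven known CO2-fixation pathways, in the KEGG
# orthology namespace. These are curated defaults shipped with the package
# (editable; pass your own file to load_pathway_definitions()). key_genes are
# the diagnostic enzymes of each pathway: RuBisCO for CBB, the CO
# dehydrogenase/acetyl-CoA synthase core for WL, ATP-citrate lyase for rTCA,
# malonyl-CoA reductase and propionyl-CoA synthase for the 3-HP bicycle,
# 4-hydroxybutyryl-CoA dehydratase for the two 4-HB routes, and citrate
# synthase for roTCA.
pathways:
  - name: CBB
    label: Calvin-Benson-Bassham reductive pentose phosphate cycle
    essential_genes:
      [K01601, K01602, K00855, K00927, K00134, K01623, K03841, K00615,
       K01807, K01783]
    key_genes: [K01601]
  - name: WL
    label: Reductive acetyl-CoA (Wood-Ljungdahl) pathway
    essential_genes:
      [K00123, K01938, K01491, K00297, K15023, K00198, K14138, K00197,
       K00194]
    key_genes: [K00198, K14138]
  - name: rTCA
    label: Reductive tricarboxylic acid cycle
    essential_genes:
      [K15230, K15231, K00174, K00175, K01902, K01903, K00239, K01679,
       K00024, K00169, K00170, K01959, K01960]
    key_genes: [K15230, K15231]
  - name: 3-HP
    label: 3-hydroxypropionate bicycle
    essential_genes:
      [K02160, K01961, K01962, K01963, K14468, K14469, K05606, K01847,
       K14471, K14472, K08691, K14449, K14470, K09709]
    key_genes: [K14468, K14469]
  - name: 3-HP/4-HB
    label: 3-hydroxypropionate/4-hydroxybutyrate cycle
    essential_genes:
      [K01964, K18602, K15019, K15020, K05606, K01847, K14465, K14466,
       K14534, K00626]
    key_genes: [K14534]
  - name: DC/4-HB
    label: Dicarboxylate/4-hydroxybutyrate cycle
    essential_genes:
      [K00169, K00170, K00171, K00172, K01007, K01595, K00024, K01679,
       K01902, K01903, K18602, K14465, K14466, K14534, K00626]
    key_genes: [K14534]
  - name: roTCA
    label: Reversed oxidative tricarboxylic acid cycle
    essential_genes:
      [K01647, K01681, K00031, K00174, K00175, K01902, K01903, K00239,
       K00240, K00241, K01679, K00024]
    key_genes: [K01647]
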