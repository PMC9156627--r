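# Hierarchical brain-region tree for semiology localization.
# Top level is fixed; additional descendants may be added under any node.
# Junctions are flat data-entry categories whose mass is redistributed to
# their constituent top-level lobes before analysis. Standalone nodes are
# kept outside the lobe hierarchy.
top_level:
  - Temporal
  - Frontal
  - Parietal
  - Occipital
  - Cingulate
  - Insula
  - Hypothalamus
  - Cerebellum
children:
  Temporal:
    - Mesial Temporal
    - Anterior Temporal
    - Lateral Temporal
    - Posterior Temporal
    - Basal Temporal
junctions:
  Frontotemporal: [Frontal, Temporal]
  Temporo-occipital: [Temporal, Occipital]
  Temporo-parietal: [Temporal, Parietal]
  Fronto-temporo-parietal: [Frontal, Temporal, Parietal]
  Temporo-parieto-occipital: [Temporal, Parietal, Occipital]
  Parieto-occipital: [Parietal, Occipital]
  Fronto-parietal: [Frontal, Parietal]
  Perisylvian: [Frontal, Temporal, Parietal]
standalone:
  - Subcallosal cortex
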