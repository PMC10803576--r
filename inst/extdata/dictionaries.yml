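cell_type:
- canonical: macrophage
  variants:
  - macrophage
- canonical: dendritic cells
  variants:
  - dendritic cell
- canonical: monocyte
  variants:
  - monocyte
- canonical: T-cell
  variants:
  - T-cell
- canonical: T-reg
  variants:
  - T-reg
  - Treg
  - regulatory T
- canonical: B-Cell
  variants:
  - B-cell
- canonical: fibroblast
  variants:
  - fibroblast
- canonical: osteoclast
  variants:
  - osteoclast
- canonical: osteoblast
  variants:
  - osteoblast
- canonical: endothelial
  variants:
  - endothelial
- canonical: epithelial
  variants:
  - epithelial
- canonical: chondrocyte
  variants:
  - chondrocyte
- canonical: nerve
  variants:
  - nerve
- canonical: neuron
  variants:
  - neuron
cytokine:
- canonical: GM-CSF
  variants:
  - GM-CSF
- canonical: IL-1
  variants:
  - IL-1
  - interleukin-1
- canonical: IL-2
  variants:
  - IL-2
  - interleukin-2
- canonical: IL-6
  variants:
  - IL-6
  - interleukin-6
- canonical: IL-8
  variants:
  - IL-8
  - interleukin-8
- canonical: IL-18
  variants:
  - IL-18
  - interleukin-18
- canonical: IL-17
  variants:
  - IL-17
  - interleukin-17
- canonical: IL-10
  variants:
  - IL-10
  - interleukin-10
- canonical: TNF
  variants:
  - TNF
  - tumor necrosis factor
  - tumour necrosis factor
- canonical: RANKL
  variants:
  - RANKL
- canonical: interleukin
  variants:
  - interleukin
process:
- canonical: angiogenesis
  variants:
  - angiogenesis
- canonical: apoptosis
  variants:
  - apoptosis
- canonical: autoantibody
  variants:
  - autoantibody
- canonical: biomarker
  variants:
  - biomarker
- canonical: degeneration
  variants:
  - degeneration
- canonical: diagnosis
  variants:
  - diagnosis
- canonical: fatigue
  variants:
  - fatigue
- canonical: fibrosis
  variants:
  - fibrosis
- canonical: inflammation
  variants:
  - inflammation
- canonical: invasion
  variants:
  - invasion
- canonical: metabolism
  variants:
  - metabolism
- canonical: migration
  variants:
  - migration
- canonical: pain
  variants:
  - pain
- canonical: proliferation
  variants:
  - proliferation
- canonical: therapy
  variants:
  - therapy
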