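# Lobe assignment for the 68-region Desikan-Killiany cortical parcellation.
# Regions 1-34 left hemisphere, 35-68 right, alphabetical within hemisphere.
regions:
  - index: 1
    label: lh_bankssts
    lobe: temporal
  - index: 2
    label: lh_caudalanteriorcingulate
    lobe: limbic
  - index: 3
    label: lh_caudalmiddlefrontal
    lobe: frontal
  - index: 4
    label: lh_cuneus
    lobe: occipital
  - index: 5
    label: lh_entorhinal
    lobe: temporal
  - index: 6
    label: lh_fusiform
    lobe: temporal
  - index: 7
    label: lh_inferiorparietal
    lobe: parietal
  - index: 8
    label: lh_inferiortemporal
    lobe: temporal
  - index: 9
    label: lh_isthmuscingulate
    lobe: limbic
  - index: 10
    label: lh_lateraloccipital
    lobe: occipital
  - index: 11
    label: lh_lateralorbitofrontal
    lobe: frontal
  - index: 12
    label: lh_lingual
    lobe: occipital
  - index: 13
    label: lh_medialorbitofrontal
    lobe: frontal
  - index: 14
    label: lh_middletemporal
    lobe: temporal
  - index: 15
    label: lh_parahippocampal
    lobe: temporal
  - index: 16
    label: lh_paracentral
    lobe: frontal
  - index: 17
    label: lh_parsopercularis
    lobe: frontal
  - index: 18
    label: lh_parsorbitalis
    lobe: frontal
  - index: 19
    label: lh_parstriangularis
    lobe: frontal
  - index: 20
    label: lh_pericalcarine
    lobe: occipital
  - index: 21
    label: lh_postcentral
    lobe: parietal
  - index: 22
    label: lh_posteriorcingulate
    lobe: limbic
  - index: 23
    label: lh_precentral
    lobe: frontal
  - index: 24
    label: lh_precuneus
    lobe: parietal
  - index: 25
    label: lh_rostralanteriorcingulate
    lobe: limbic
  - index: 26
    label: lh_rostralmiddlefrontal
    lobe: frontal
  - index: 27
    label: lh_superiorfrontal
    lobe: frontal
  - index: 28
    label: lh_superiorparietal
    lobe: parietal
  - index: 29
    label: lh_superiortemporal
    lobe: temporal
  - index: 30
    label: lh_supramarginal
    lobe: parietal
  - index: 31
    label: lh_frontalpole
    lobe: frontal
  - index: 32
    label: lh_temporalpole
    lobe: temporal
  - index: 33
    label: lh_transversetemporal
    lobe: temporal
  - index: 34
    label: lh_insula
    lobe: insular
  - index: 35
    label: rh_bankssts
    lobe: temporal
  - index: 36
    label: rh_caudalanteriorcingulate
    lobe: limbic
  - index: 37
    label: rh_caudalmiddlefrontal
    lobe: frontal
  - index: 38
    label: rh_cuneus
    lobe: occipital
  - index: 39
    label: rh_entorhinal
    lobe: temporal
  - index: 40
    label: rh_fusiform
    lobe: temporal
  - index: 41
    label: rh_inferiorparietal
    lobe: parietal
  - index: 42
    label: rh_inferiortemporal
    lobe: temporal
  - index: 43
    label: rh_isthmuscingulate
    lobe: limbic
  - index: 44
    label: rh_lateraloccipital
    lobe: occipital
  - index: 45
    label: rh_lateralorbitofrontal
    lobe: frontal
  - index: 46
    label: rh_lingual
    lobe: occipital
  - index: 47
    label: rh_medialorbitofrontal
    lobe: frontal
  - index: 48
    label: rh_middletemporal
    lobe: temporal
  - index: 49
    label: rh_parahippocampal
    lobe: temporal
  - index: 50
    label: rh_paracentral
    lobe: frontal
  - index: 51
    label: rh_parsopercularis
    lobe: frontal
  - index: 52
    label: rh_parsorbitalis
    lobe: frontal
  - index: 53
    label: rh_parstriangularis
    lobe: frontal
  - index: 54
    label: rh_pericalcarine
    lobe: occipital
  - index: 55
    label: rh_postcentral
    lobe: parietal
  - index: 56
    label: rh_posteriorcingulate
    lobe: limbic
  - index: 57
    label: rh_precentral
    lobe: frontal
  - index: 58
    label: rh_precuneus
    lobe: parietal
  - index: 59
    label: rh_rostralanteriorcingulate
    lobe: limbic
  - index: 60
    label: rh_rostralmiddlefrontal
    lobe: frontal
  - index: 61
    label: rh_superiorfrontal
    lobe: frontal
  - index: 62
    label: rh_superiorparietal
    lobe: parietal
  - index: 63
    label: rh_superiortemporal
    lobe: temporal
  - index: 64
    label: rh_supramarginal
    lobe: parietal
  - index: 65
    label: rh_frontalpole
    lobe: frontal
  - index: 66
    label: rh_temporalpole
    lobe: temporal
  - index: 67
    label: rh_transversetemporal
    lobe: temporal
  - index: 68
    label: rh_insula
    lobe: insular
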