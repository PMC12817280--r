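{
  "version": "1.0",
  "reference_scale": "DSS",
  "tables": {
    "reference_shifts": {
      "citation": "Wang Y, Jardetzky O (2002) Probability-based protein secondary structure identification using combined NMR chemical-shift data. Protein Sci 11:852-861",
      "note": "Per-residue Calpha/Cbeta mean chemical shifts and standard deviations for alpha-helix, beta-sheet and random-coil classes, transcribed for the residue types of the eADF4 repeat (G,S,A,P,Y,E,N,Q)."
    },
    "glu_protonation": {
      "citation": "Platzer G, Okon M, McIntosh LP (2014) pH-dependent random coil 1H, 13C, and 15N chemical shifts of the ionizable amino acids. J Biomol NMR 60:109-129",
      "note": "Expected Glu Cgamma/Cdelta cross-peak positions for the deprotonated (36.1/183.8 ppm) and protonated (32.7/179.7 ppm) side chain."
    },
    "proline_isomer": {
      "citation": "Poznanski J et al., conformation-dependent 13C shifts of proline cis/trans isomers",
      "note": "Canonical Cbeta/Cgamma shifts; the cis isomer shows a larger Cbeta-Cgamma separation (~9.6 ppm) than trans (~4.5 ppm). Default discriminator threshold 7.0 ppm, midway between the canonical separations.",
      "delta_bg_threshold_ppm": 7.0
    },
    "random_coil_corrections": {
      "citation": "Schwarzinger S et al. (2001) Sequence-dependent correction of random coil NMR chemical shifts. J Am Chem Soc 123:2970-2978",
      "note": "Additive neighbour corrections to random-coil shifts; at minimum the shielding of Gly Calpha by a preceding Pro."
    }
  }
}
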