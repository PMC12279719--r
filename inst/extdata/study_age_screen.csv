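hemisphere,region,lobe,r,p
left,Pars orbitalis,Frontal,-0.44,<0.001
left,Pars opercularis,Frontal,-0.43,<0.001
left,Rostral middle frontal gyrus,Frontal,-0.42,<0.001
left,Pars triangularis,Frontal,-0.39,<0.001
left,Superior frontal gyrus,Frontal,-0.33,0.002
left,Lateral orbitofrontal gyrus,Frontal,-0.33,0.002
left,Precentral gyrus,Frontal,-0.31,0.004
left,Caudal middle frontal,Frontal,-0.27,0.014
left,Medial orbitofrontal gyrus,Frontal,-0.26,0.017
left,Superior parietal gyrus,Parietal,-0.47,<0.001
left,Precuneus,Parietal,-0.41,<0.001
left,Supramarginal gyrus,Parietal,-0.38,<0.001
left,Inferior parietal gyrus,Parietal,-0.37,0.001
left,Postcentral gyrus,Parietal,-0.33,0.002
left,Middle temporal gyrus,Temporal,-0.34,0.002
left,Superior temporal gyrus,Temporal,-0.31,0.006
left,Transverse temporal gyrus,Temporal,-0.27,0.014
left,Inferior temporal gyrus,Temporal,-0.25,0.025
left,Lateral occipital gyrus,Occipital,-0.31,0.004
left,Hippocampus,Subcortical,-0.38,<0.001
left,Thalamus,Subcortical,-0.34,0.002
right,Rostral middle frontal gyrus,Frontal,-0.54,<0.001
right,Pars triangularis,Frontal,-0.44,<0.001
right,Pars orbitalis,Frontal,-0.43,<0.001
right,Superior frontal gyrus,Frontal,-0.42,<0.001
right,Precentral gyrus,Frontal,-0.34,0.002
right,Caudal middle frontal gyrus,Frontal,-0.32,0.004
right,Pars opercularis,Frontal,-0.32,0.004
right,Lateral orbitofrontal gyrus,Frontal,-0.26,0.021
right,Paracentral gyrus,Frontal,-0.25,0.021
right,Superior parietal gyrus,Parietal,-0.47,<0.001
right,Precuneus,Parietal,-0.46,<0.001
right,Postcentral gyrus,Parietal,-0.43,<0.001
right,Inferior parietal gyrus,Parietal,-0.38,<0.001
right,Entorhinal cortex,Temporal,-0.37,<0.001
right,Superior temporal gyrus,Temporal,-0.37,<0.001
right,Inferior temporal gyrus,Temporal,-0.35,0.001
right,Fusiform gyrus,Temporal,-0.26,0.016
right,Banks of the superior temporal sulcus,Temporal,-0.25,0.025
right,Lateral occipital gyrus,Occipital,-0.37,<0.001
right,Cuneus,Occipital,-0.27,0.013
right,Hippocampus,Subcortical,-0.47,<0.001
right,Accumbens,Subcortical,-0.41,<0.001
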