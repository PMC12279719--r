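hemisphere,region,lobe,r,p
left,Superior frontal gyrus,Frontal,0.35,0.001
left,Medial orbitofrontal gyrus,Frontal,0.35,0.001
left,Rostral middle frontal gyrus,Frontal,0.34,0.002
left,Lateral orbitofrontal gyrus,Frontal,0.33,0.003
left,Pars opercularis,Frontal,0.31,0.005
left,Pars orbitalis,Frontal,0.29,0.007
left,Frontal pole,Frontal,0.26,0.017
left,Precentral gyrus,Frontal,0.25,0.022
left,Precuneus,Parietal,0.41,<0.001
left,Superior parietal gyrus,Parietal,0.33,0.002
left,Inferior parietal gyrus,Parietal,0.31,0.004
left,Supramarginal gyrus,Parietal,0.29,0.007
left,Postcentral gyrus,Parietal,0.27,0.013
left,Middle temporal gyrus,Temporal,0.31,0.004
left,Transverse temporal gyrus,Temporal,0.28,0.011
left,Banks of the Superior Temporal Sulcus,Temporal,0.25,0.024
left,Superior temporal gyrus,Temporal,0.25,0.025
left,Lingual gyrus,Occipital,0.38,<0.001
left,Cuneus,Occipital,0.26,0.018
left,Hippocampus,Subcortical,0.37,<0.001
left,Thalamus,Subcortical,0.36,<0.001
left,Putamen,Subcortical,0.29,0.007
left,Accumbens,Subcortical,0.28,0.012
left,Caudate,Subcortical,0.26,0.019
right,Pars orbitalis,Frontal,0.36,<0.001
right,Superior frontal gyrus,Frontal,0.33,0.003
right,Pars triangularis,Frontal,0.31,0.005
right,Medial orbitofrontal gyrus,Frontal,0.31,0.006
right,Rostral middle frontal gyrus,Frontal,0.29,0.008
right,Lateral orbitofrontal gyrus,Frontal,0.28,0.011
right,Frontal pole,Frontal,0.28,0.012
right,Precentral gyrus,Frontal,0.27,0.012
right,Precuneus,Parietal,0.42,<0.001
right,Superior parietal gyrus,Parietal,0.29,0.008
right,Postcentral gyrus,Parietal,0.27,0.013
right,Posterior cingulate,Parietal,-0.25,0.025
right,Inferior parietal gyrus,Parietal,0.25,0.027
right,Inferior temporal gyrus,Temporal,0.33,0.002
right,Fusiform gyrus,Temporal,0.29,0.008
right,Middle temporal gyrus,Temporal,0.28,0.011
right,Cuneus,Occipital,0.29,0.007
right,Lateral occipital gyrus,Occipital,0.27,0.016
right,Hippocampus,Subcortical,0.41,<0.001
right,Thalamus,Subcortical,0.32,0.003
right,Accumbens,Subcortical,0.31,0.005
right,Caudate,Subcortical,0.25,0.023
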