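label,hemisphere,group
Banks of the superior temporal sulcus,left,temporal
Caudal anterior cingulate,left,insula-cingulate
Caudal middle frontal gyrus,left,frontal
Cuneus,left,occipital
Entorhinal cortex,left,temporal
Fusiform gyrus,left,temporal
Inferior parietal gyrus,left,parietal
Inferior temporal gyrus,left,temporal
Isthmus cingulate,left,insula-cingulate
Lateral occipital gyrus,left,occipital
Lateral orbitofrontal gyrus,left,frontal
Lingual gyrus,left,occipital
Medial orbitofrontal gyrus,left,frontal
Middle temporal gyrus,left,temporal
Parahippocampal gyrus,left,temporal
Paracentral gyrus,left,frontal
Pars opercularis,left,frontal
Pars orbitalis,left,frontal
Pars triangularis,left,frontal
Pericalcarine cortex,left,occipital
Postcentral gyrus,left,parietal
Posterior cingulate,left,insula-cingulate
Precentral gyrus,left,frontal
Precuneus,left,parietal
Rostral anterior cingulate,left,insula-cingulate
Rostral middle frontal gyrus,left,frontal
Superior frontal gyrus,left,frontal
Superior parietal gyrus,left,parietal
Superior temporal gyrus,left,temporal
Supramarginal gyrus,left,parietal
Frontal pole,left,frontal
Temporal pole,left,temporal
Transverse temporal gyrus,left,temporal
Insula,left,insula-cingulate
Banks of the superior temporal sulcus,right,temporal
Caudal anterior cingulate,right,insula-cingulate
Caudal middle frontal gyrus,right,frontal
Cuneus,right,occipital
Entorhinal cortex,right,temporal
Fusiform gyrus,right,temporal
Inferior parietal gyrus,right,parietal
Inferior temporal gyrus,right,temporal
Isthmus cingulate,right,insula-cingulate
Lateral occipital gyrus,right,occipital
Lateral orbitofrontal gyrus,right,frontal
Lingual gyrus,right,occipital
Medial orbitofrontal gyrus,right,frontal
Middle temporal gyrus,right,temporal
Parahippocampal gyrus,right,temporal
Paracentral gyrus,right,frontal
Pars opercularis,right,frontal
Pars orbitalis,right,frontal
Pars triangularis,right,frontal
Pericalcarine cortex,right,occipital
Postcentral gyrus,right,parietal
Posterior cingulate,right,insula-cingulate
Precentral gyrus,right,frontal
Precuneus,right,parietal
Rostral anterior cingulate,right,insula-cingulate
Rostral middle frontal gyrus,right,frontal
Superior frontal gyrus,right,frontal
Superior parietal gyrus,right,parietal
Superior temporal gyrus,right,temporal
Supramarginal gyrus,right,parietal
Frontal pole,right,frontal
Temporal pole,right,temporal
Transverse temporal gyrus,right,temporal
Insula,right,insula-cingulate
Thalamus,left,subcortical
Caudate,left,subcortical
Putamen,left,subcortical
Pallidum,left,subcortical
Hippocampus,left,subcortical
Amygdala,left,subcortical
Accumbens,left,subcortical
Thalamus,right,subcortical
Caudate,right,subcortical
Putamen,right,subcortical
Pallidum,right,subcortical
Hippocampus,right,subcortical
Amygdala,right,subcortical
Accumbens,right,subcortical
Cerebellum cortex,left,cerebellum
Cerebellum cortex,right,cerebellum
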