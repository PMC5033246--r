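label_name,class
cerebral aqueduct,CSF
lateral ventricles,CSF
third ventricle,CSF
fourth ventricle,CSF
amygdala,GM
auditory cortex,GM
cerebellar cortex,GM
cortex general,GM
dentate gyrus,GM
entorhinal cortex,GM
frontal cortex,GM
general basal ganglia,GM
hippocampus CA1,GM
hippocampus CA3,GM
hippocampus general,GM
hypothalamus,GM
lateral olfactory tract,GM
midbrain (remainder),GM
motor cortex,GM
olfactory system,GM
periaqueductal grey,GM
perirhinal cortex,GM
septum,GM
somatosensory cortex,GM
substantia nigra,GM
visual cortex,GM
caudate putamen (striatum),GM/WM mixture
superior & inferior colliculi,GM/WM mixture
thalamus,GM/WM mixture
anterior commissure,WM
cerebellar lobules,WM
cerebral peduncle,WM
corpus callosum,WM
fornix system,WM
internal capsule,WM
medulla,WM
optic nerve,WM
pons,WM
pituitary,excluded
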