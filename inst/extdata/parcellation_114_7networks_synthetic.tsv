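# 114-region parcellation: 100 cortical regions in 7 canonical RSNs + 14 subcortical
# SYNTHETIC stand-in label table: region counts per network are plausible,
# not copied from any published atlas.
label	network
LH_visual_1	visual
LH_visual_2	visual
LH_visual_3	visual
LH_visual_4	visual
LH_visual_5	visual
LH_visual_6	visual
LH_visual_7	visual
RH_visual_1	visual
RH_visual_2	visual
RH_visual_3	visual
RH_visual_4	visual
RH_visual_5	visual
RH_visual_6	visual
RH_visual_7	visual
LH_somatomotor_1	somatomotor
LH_somatomotor_2	somatomotor
LH_somatomotor_3	somatomotor
LH_somatomotor_4	somatomotor
LH_somatomotor_5	somatomotor
LH_somatomotor_6	somatomotor
LH_somatomotor_7	somatomotor
LH_somatomotor_8	somatomotor
RH_somatomotor_1	somatomotor
RH_somatomotor_2	somatomotor
RH_somatomotor_3	somatomotor
RH_somatomotor_4	somatomotor
RH_somatomotor_5	somatomotor
RH_somatomotor_6	somatomotor
RH_somatomotor_7	somatomotor
RH_somatomotor_8	somatomotor
LH_dorsal_attention_1	dorsal_attention
LH_dorsal_attention_2	dorsal_attention
LH_dorsal_attention_3	dorsal_attention
LH_dorsal_attention_4	dorsal_attention
LH_dorsal_attention_5	dorsal_attention
LH_dorsal_attention_6	dorsal_attention
LH_dorsal_attention_7	dorsal_attention
RH_dorsal_attention_1	dorsal_attention
RH_dorsal_attention_2	dorsal_attention
RH_dorsal_attention_3	dorsal_attention
RH_dorsal_attention_4	dorsal_attention
RH_dorsal_attention_5	dorsal_attention
RH_dorsal_attention_6	dorsal_attention
LH_ventral_attention_1	ventral_attention
LH_ventral_attention_2	ventral_attention
LH_ventral_attention_3	ventral_attention
LH_ventral_attention_4	ventral_attention
LH_ventral_attention_5	ventral_attention
LH_ventral_attention_6	ventral_attention
RH_ventral_attention_1	ventral_attention
RH_ventral_attention_2	ventral_attention
RH_ventral_attention_3	ventral_attention
RH_ventral_attention_4	ventral_attention
RH_ventral_attention_5	ventral_attention
RH_ventral_attention_6	ventral_attention
LH_limbic_1	limbic
LH_limbic_2	limbic
LH_limbic_3	limbic
LH_limbic_4	limbic
LH_limbic_5	limbic
RH_limbic_1	limbic
RH_limbic_2	limbic
RH_limbic_3	limbic
RH_limbic_4	limbic
RH_limbic_5	limbic
LH_frontoparietal_1	frontoparietal
LH_frontoparietal_2	frontoparietal
LH_frontoparietal_3	frontoparietal
LH_frontoparietal_4	frontoparietal
LH_frontoparietal_5	frontoparietal
LH_frontoparietal_6	frontoparietal
LH_frontoparietal_7	frontoparietal
LH_frontoparietal_8	frontoparietal
LH_frontoparietal_9	frontoparietal
RH_frontoparietal_1	frontoparietal
RH_frontoparietal_2	frontoparietal
RH_frontoparietal_3	frontoparietal
RH_frontoparietal_4	frontoparietal
RH_frontoparietal_5	frontoparietal
RH_frontoparietal_6	frontoparietal
RH_frontoparietal_7	frontoparietal
RH_frontoparietal_8	frontoparietal
LH_default_mode_1	default_mode
LH_default_mode_2	default_mode
LH_default_mode_3	default_mode
LH_default_mode_4	default_mode
LH_default_mode_5	default_mode
LH_default_mode_6	default_mode
LH_default_mode_7	default_mode
LH_default_mode_8	default_mode
LH_default_mode_9	default_mode
RH_default_mode_1	default_mode
RH_default_mode_2	default_mode
RH_default_mode_3	default_mode
RH_default_mode_4	default_mode
RH_default_mode_5	default_mode
RH_default_mode_6	default_mode
RH_default_mode_7	default_mode
RH_default_mode_8	default_mode
RH_default_mode_9	default_mode
L_Thalamus	subcortical
L_Caudate	subcortical
L_Putamen	subcortical
L_Pallidum	subcortical
L_Hippocampus	subcortical
L_Amygdala	subcortical
L_Accumbens	subcortical
R_Thalamus	subcortical
R_Caudate	subcortical
R_Putamen	subcortical
R_Pallidum	subcortical
R_Hippocampus	subcortical
R_Amygdala	subcortical
R_Accumbens	subcortical
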