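# 224-region parcellation: 210 cortical regions in 7 canonical RSNs + 14 subcortical
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
LH_visual_8	visual
LH_visual_9	visual
LH_visual_10	visual
LH_visual_11	visual
LH_visual_12	visual
LH_visual_13	visual
LH_visual_14	visual
LH_visual_15	visual
RH_visual_1	visual
RH_visual_2	visual
RH_visual_3	visual
RH_visual_4	visual
RH_visual_5	visual
RH_visual_6	visual
RH_visual_7	visual
RH_visual_8	visual
RH_visual_9	visual
RH_visual_10	visual
RH_visual_11	visual
RH_visual_12	visual
RH_visual_13	visual
RH_visual_14	visual
RH_visual_15	visual
LH_somatomotor_1	somatomotor
LH_somatomotor_2	somatomotor
LH_somatomotor_3	somatomotor
LH_somatomotor_4	somatomotor
LH_somatomotor_5	somatomotor
LH_somatomotor_6	somatomotor
LH_somatomotor_7	somatomotor
LH_somatomotor_8	somatomotor
LH_somatomotor_9	somatomotor
LH_somatomotor_10	somatomotor
LH_somatomotor_11	somatomotor
LH_somatomotor_12	somatomotor
LH_somatomotor_13	somatomotor
LH_somatomotor_14	somatomotor
LH_somatomotor_15	somatomotor
LH_somatomotor_16	somatomotor
RH_somatomotor_1	somatomotor
RH_somatomotor_2	somatomotor
RH_somatomotor_3	somatomotor
RH_somatomotor_4	somatomotor
RH_somatomotor_5	somatomotor
RH_somatomotor_6	somatomotor
RH_somatomotor_7	somatomotor
RH_somatomotor_8	somatomotor
RH_somatomotor_9	somatomotor
RH_somatomotor_10	somatomotor
RH_somatomotor_11	somatomotor
RH_somatomotor_12	somatomotor
RH_somatomotor_13	somatomotor
RH_somatomotor_14	somatomotor
RH_somatomotor_15	somatomotor
RH_somatomotor_16	somatomotor
LH_dorsal_attention_1	dorsal_attention
LH_dorsal_attention_2	dorsal_attention
LH_dorsal_attention_3	dorsal_attention
LH_dorsal_attention_4	dorsal_attention
LH_dorsal_attention_5	dorsal_attention
LH_dorsal_attention_6	dorsal_attention
LH_dorsal_attention_7	dorsal_attention
LH_dorsal_attention_8	dorsal_attention
LH_dorsal_attention_9	dorsal_attention
LH_dorsal_attention_10	dorsal_attention
LH_dorsal_attention_11	dorsal_attention
LH_dorsal_attention_12	dorsal_attention
LH_dorsal_attention_13	dorsal_attention
LH_dorsal_attention_14	dorsal_attention
RH_dorsal_attention_1	dorsal_attention
RH_dorsal_attention_2	dorsal_attention
RH_dorsal_attention_3	dorsal_attention
RH_dorsal_attention_4	dorsal_attention
RH_dorsal_attention_5	dorsal_attention
RH_dorsal_attention_6	dorsal_attention
RH_dorsal_attention_7	dorsal_attention
RH_dorsal_attention_8	dorsal_attention
RH_dorsal_attention_9	dorsal_attention
RH_dorsal_attention_10	dorsal_attention
RH_dorsal_attention_11	dorsal_attention
RH_dorsal_attention_12	dorsal_attention
RH_dorsal_attention_13	dorsal_attention
RH_dorsal_attention_14	dorsal_attention
LH_ventral_attention_1	ventral_attention
LH_ventral_attention_2	ventral_attention
LH_ventral_attention_3	ventral_attention
LH_ventral_attention_4	ventral_attention
LH_ventral_attention_5	ventral_attention
LH_ventral_attention_6	ventral_attention
LH_ventral_attention_7	ventral_attention
LH_ventral_attention_8	ventral_attention
LH_ventral_attention_9	ventral_attention
LH_ventral_attention_10	ventral_attention
LH_ventral_attention_11	ventral_attention
LH_ventral_attention_12	ventral_attention
LH_ventral_attention_13	ventral_attention
RH_ventral_attention_1	ventral_attention
RH_ventral_attention_2	ventral_attention
RH_ventral_attention_3	ventral_attention
RH_ventral_attention_4	ventral_attention
RH_ventral_attention_5	ventral_attention
RH_ventral_attention_6	ventral_attention
RH_ventral_attention_7	ventral_attention
RH_ventral_attention_8	ventral_attention
RH_ventral_attention_9	ventral_attention
RH_ventral_attention_10	ventral_attention
RH_ventral_attention_11	ventral_attention
RH_ventral_attention_12	ventral_attention
RH_ventral_attention_13	ventral_attention
LH_limbic_1	limbic
LH_limbic_2	limbic
LH_limbic_3	limbic
LH_limbic_4	limbic
LH_limbic_5	limbic
LH_limbic_6	limbic
LH_limbic_7	limbic
LH_limbic_8	limbic
LH_limbic_9	limbic
LH_limbic_10	limbic
LH_limbic_11	limbic
LH_limbic_12	limbic
RH_limbic_1	limbic
RH_limbic_2	limbic
RH_limbic_3	limbic
RH_limbic_4	limbic
RH_limbic_5	limbic
RH_limbic_6	limbic
RH_limbic_7	limbic
RH_limbic_8	limbic
RH_limbic_9	limbic
RH_limbic_10	limbic
RH_limbic_11	limbic
RH_limbic_12	limbic
LH_frontoparietal_1	frontoparietal
LH_frontoparietal_2	frontoparietal
LH_frontoparietal_3	frontoparietal
LH_frontoparietal_4	frontoparietal
LH_frontoparietal_5	frontoparietal
LH_frontoparietal_6	frontoparietal
LH_frontoparietal_7	frontoparietal
LH_frontoparietal_8	frontoparietal
LH_frontoparietal_9	frontoparietal
LH_frontoparietal_10	frontoparietal
LH_frontoparietal_11	frontoparietal
LH_frontoparietal_12	frontoparietal
LH_frontoparietal_13	frontoparietal
LH_frontoparietal_14	frontoparietal
LH_frontoparietal_15	frontoparietal
LH_frontoparietal_16	frontoparietal
LH_frontoparietal_17	frontoparietal
RH_frontoparietal_1	frontoparietal
RH_frontoparietal_2	frontoparietal
RH_frontoparietal_3	frontoparietal
RH_frontoparietal_4	frontoparietal
RH_frontoparietal_5	frontoparietal
RH_frontoparietal_6	frontoparietal
RH_frontoparietal_7	frontoparietal
RH_frontoparietal_8	frontoparietal
RH_frontoparietal_9	frontoparietal
RH_frontoparietal_10	frontoparietal
RH_frontoparietal_11	frontoparietal
RH_frontoparietal_12	frontoparietal
RH_frontoparietal_13	frontoparietal
RH_frontoparietal_14	frontoparietal
RH_frontoparietal_15	frontoparietal
RH_frontoparietal_16	frontoparietal
RH_frontoparietal_17	frontoparietal
LH_default_mode_1	default_mode
LH_default_mode_2	default_mode
LH_default_mode_3	default_mode
LH_default_mode_4	default_mode
LH_default_mode_5	default_mode
LH_default_mode_6	default_mode
LH_default_mode_7	default_mode
LH_default_mode_8	default_mode
LH_default_mode_9	default_mode
LH_default_mode_10	default_mode
LH_default_mode_11	default_mode
LH_default_mode_12	default_mode
LH_default_mode_13	default_mode
LH_default_mode_14	default_mode
LH_default_mode_15	default_mode
LH_default_mode_16	default_mode
LH_default_mode_17	default_mode
LH_default_mode_18	default_mode
RH_default_mode_1	default_mode
RH_default_mode_2	default_mode
RH_default_mode_3	default_mode
RH_default_mode_4	default_mode
RH_default_mode_5	default_mode
RH_default_mode_6	default_mode
RH_default_mode_7	default_mode
RH_default_mode_8	default_mode
RH_default_mode_9	default_mode
RH_default_mode_10	default_mode
RH_default_mode_11	default_mode
RH_default_mode_12	default_mode
RH_default_mode_13	default_mode
RH_default_mode_14	default_mode
RH_default_mode_15	default_mode
RH_default_mode_16	default_mode
RH_default_mode_17	default_mode
RH_default_mode_18	default_mode
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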