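patient_id,week_index,answer_date,blood_in_stool.present,blood_in_stool.amount,blood_in_stool.needs_urgent_care,hematuria.present,hematuria.appearance,hematuria.needs_urgent_care,blurred_vision.present,blurred_vision.limits_instrumental_adl,blurred_vision.limits_self_care,chest_pain.present,chest_pain.pain_at_rest,chest_pain.limits_instrumental_adl,chest_pain.limits_self_care,cough.present,cough.limits_instrumental_adl,cough.limits_self_care,loss_of_appetite.present,loss_of_appetite.eating_less,loss_of_appetite.significant_weight_loss,diarrhea.present,diarrhea.stools_per_day_over_baseline,diarrhea.hospitalization_level_symptoms,diarrhea.limits_self_care,dizziness.present,dizziness.limits_instrumental_adl,dizziness.limits_self_care,fatigue.present,fatigue.not_relieved_by_rest,fatigue.limits_instrumental_adl,fatigue.limits_self_care,fever.present,fever.highest_temperature,headache.present,headache.limits_instrumental_adl,headache.limits_self_care,itching.present,itching.widespread,itching.limits_instrumental_adl,itching.constant_or_limits_sleep,nausea.present,nausea.eating_less,nausea.barely_able_to_eat_or_drink,pain_in_joints.present,pain_in_joints.limits_instrumental_adl,pain_in_joints.limits_self_care,rash.present,rash.body_area,shortness_of_breath.present,shortness_of_breath.breathless_when,shortness_of_breath.needs_urgent_care,stomach_pain.present,stomach_pain.limits_instrumental_adl,stomach_pain.limits_self_care,vomiting.present,vomiting.episodes_last_24h,vomiting.needs_urgent_intervention
EX01,0,2021-03-01,FALSE,streaks_on_paper,FALSE,FALSE,slightly_discolored,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,t_38_0_to_39_0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,small_area,FALSE,moderate_exertion,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE
EX01,1,2021-03-08,FALSE,streaks_on_paper,FALSE,FALSE,slightly_discolored,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,t_38_0_to_39_0,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,small_area,FALSE,moderate_exertion,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE
EX01,2,2021-03-15,FALSE,streaks_on_paper,FALSE,FALSE,slightly_discolored,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,4,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,TRUE,FALSE,t_38_0_to_39_0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,small_area,FALSE,moderate_exertion,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE
EX02,0,2021-03-01,FALSE,streaks_on_paper,FALSE,FALSE,slightly_discolored,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,t_38_0_to_39_0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,small_area,FALSE,moderate_exertion,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE
EX02,1,2021-03-08,FALSE,streaks_on_paper,FALSE,FALSE,slightly_discolored,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,t_38_0_to_39_0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,small_area,TRUE,minimal_exertion,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE
EX02,2,2021-03-15,FALSE,streaks_on_paper,FALSE,FALSE,slightly_discolored,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,t_38_0_to_39_0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,small_area,FALSE,moderate_exertion,FALSE,FALSE,FALSE,FALSE,TRUE,0,FALSE
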