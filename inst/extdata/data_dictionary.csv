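column,type,description
id,character,participant identifier
trial,character,"trial label, A or B"
study,integer,"study indicator covariate, 1 = trial B"
group,integer,"randomised arm, 1 = intervention, 0 = wait-list control"
sex,character,female or male
age,numeric,age in years at baseline
wave,integer,"assessment point in months: 0, 3, 6"
observed,logical,FALSE when the follow-up wave was missed
mvpa_sessions,numeric,MVPA sessions per week
rt_days,numeric,resistance-training days per week (0-7)
vigorous_fraction,numeric,proportion of MVPA minutes that were vigorous (0-1)
mvpa_minutes,numeric,MVPA minutes per week
sitting_minutes,numeric,sitting minutes per day
daytime_sleepiness,numeric,"trouble staying awake rating, higher = more trouble"
sleep_quality,numeric,"overall sleep quality rating, higher = worse"
sleep_midpoint,numeric,sleep midpoint in minutes after midnight (0-1439)
sleep_variability,numeric,"sum of bed- and wake-time variability items, higher = more variable"
sleep_efficiency,numeric,sleep duration / time in bed x 100 (0-100)
sleep_duration_hours,numeric,sleep duration in hours
activity_type,numeric,"derived: 0 neither MVPA nor RT, 1 one of the two, 2 both"
sleep_timing,numeric,derived: 1 when sleep midpoint falls between 02:00 and 04:00
sleep_duration_ok,numeric,derived: 1 when sleep duration meets the 7-9 h adult guideline
dass_depression,numeric,DASS-21 depression score (doubled 0-42 scale)
dass_anxiety,numeric,DASS-21 anxiety score (doubled 0-42 scale)
dass_stress,numeric,DASS-21 stress score (doubled 0-42 scale)
qol_physical,numeric,SF-12 physical component score
qol_mental,numeric,SF-12 mental component score
energy_fatigue,numeric,energy and fatigue subscale (0-100)
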