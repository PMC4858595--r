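# Example plausibility limits per volume category over a 4-month
# (120-day) recall window. Only the hospital-days rule is anchored to the
# window length; the rest are deliberately generous round numbers within
# the range of credibility and are user-editable.
recall_days: 120
limits:
  gp_contacts: 50
  emergency_visits: 20
  hospital_days: 120
  ambulance_rides: 20
  mental_health_contacts: 60
  school_absence_hours: 500
  attendance_officer_contacts: 20
  work_absence_hours: 500
  household_hours_missed: 500
  other_activity_hours_missed: 500
  youth_family_center_contacts: 50
  family_care_contacts: 50
  police_contacts: 50
  youth_police_contacts: 50
  court_proceedings: 20
  child_protection_contacts: 50
  child_health_protection_contacts: 50
  cigarette_packs: 150
  soft_drug_units: 250
  hard_drug_units: 250
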