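# Example unit-cost table (Euro). Illustrative placeholder prices in the
# style of national costing manuals; real analyses must substitute their
# own prices and price-index factors. Reference year 2014.
reference_year: 2014
index_factors:
  2012: 0.975
  2013: 0.990
  2014: 1.000
categories:
  gp_contacts:                      {unit_price: 33.00,  price_year: 2014}
  emergency_visits:                 {unit_price: 259.00, price_year: 2012}
  hospital_days:                    {unit_price: 476.00, price_year: 2012}
  ambulance_rides:                  {unit_price: 524.00, price_year: 2012}
  mental_health_contacts:           {unit_price: 98.00,  price_year: 2013}
  school_absence_hours:             {unit_price: 5.20,   price_year: 2014}
  attendance_officer_contacts:      {unit_price: 27.00,  price_year: 2014}
  work_absence_hours:               {unit_price: 13.50,  price_year: 2014}
  household_hours_missed:           {unit_price: 13.00,  price_year: 2014}
  other_activity_hours_missed:      {unit_price: 13.00,  price_year: 2014}
  youth_family_center_contacts:     {unit_price: 31.00,  price_year: 2013}
  family_care_contacts:             {unit_price: 41.00,  price_year: 2013}
  police_contacts:                  {unit_price: 178.00, price_year: 2013}
  youth_police_contacts:            {unit_price: 178.00, price_year: 2013}
  court_proceedings:                {unit_price: 390.00, price_year: 2013}
  child_protection_contacts:        {unit_price: 152.00, price_year: 2013}
  child_health_protection_contacts: {unit_price: 152.00, price_year: 2013}
  cigarette_packs:                  {unit_price: 6.00,   price_year: 2014}
  soft_drug_units:                  {unit_price: 9.00,   price_year: 2014}
  hard_drug_units:                  {unit_price: 25.00,  price_year: 2014}
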