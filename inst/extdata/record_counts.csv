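dataset,stream,n_records,period
plant_health_inspections,presence_absence,17147,2000-2022
public_reports,presence_background,1724,2000-2022
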