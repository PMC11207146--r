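quantity,value
individual_migrants_total,767
individual_senders,277
individuals_aged_15_59,1994
households_total,458
households_receiving,233
households_not_receiving,225
destination_cities_total,87
destination_cities_with_remittance,55
destination_provinces_total,36
destination_provinces_with_remittance,24
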