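constraint_id,description,level,attribute,value,lb,ub
R01,Number of items per test (test length),item_count,,,36,36
R02,Number of units per test,unit_count,,,12,12
R03,Number of items per unit,per_unit_count,,,3,3
R04,Items of cognitive process Scan,item_count,cognitive_process,Scan,4,6
R05,Items of cognitive process Represent,item_count,cognitive_process,Represent,4,6
R06,Items of cognitive process Integrate (single text),item_count,cognitive_process,Integrate_single,4,6
R07,Items of cognitive process Integrate (multiple texts),item_count,cognitive_process,Integrate_multiple,4,6
R08,Items of cognitive processes Reflect and Assess,item_count,cognitive_process,Reflect|Assess,6,8
R09,Items of cognitive process Corroborate,item_count,cognitive_process,Corroborate,3,5
R10,Items of cognitive process Search,item_count,cognitive_process,Search,3,5
R11,Human-coded items,item_count,coding,human,7,17
R12,Single-text items,item_count,text_type,single,24,35
R13,Multiple-text items,item_count,text_type,multiple,1,13
R14,Trend items,item_count,trend,trend,3,21
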