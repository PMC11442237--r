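constraint_id,description,level,attribute,value,lb,ub
M01,Number of items per test (test length),item_count,,,24,24
M02,Number of units per test,unit_count,,,10,10
M03,Number of items per unit,per_unit_count,,,1,4
M04,Items of cognitive process Employ,item_count,cognitive_process,Employ,7,9
M05,Items of cognitive process Formulate,item_count,cognitive_process,Formulate,7,9
M06,Items of cognitive process Interpret,item_count,cognitive_process,Interpret,7,9
M07,Items of content category Change,item_count,content,Change,5,7
M08,Items of content category Space,item_count,content,Space,5,7
M09,Items of content category Quantity,item_count,content,Quantity,5,7
M10,Items of content category Uncertainty,item_count,content,Uncertainty,5,7
M11,Human-coded items,item_count,coding,human,4,8
M12,Machine-coded items,item_count,coding,machine,16,18
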