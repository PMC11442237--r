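constraint_id,description,level,attribute,value,lb,ub
S01,Number of items per test (test length),item_count,,,36,36
S02,Number of units per test,unit_count,,,12,12
S03,Number of items per unit,per_unit_count,,,1,5
S04,Items of competency Evaluate,item_count,competency,Evaluate,7,11
S05,Items of competency Explain,item_count,competency,Explain,14,18
S06,Items of competency Interpret,item_count,competency,Interpret,11,14
S07,Items of knowledge Content,item_count,knowledge,Content,19,24
S08,Items of knowledge Epistemic,item_count,knowledge,Epistemic,4,8
S09,Items of knowledge Procedural,item_count,knowledge,Procedural,7,11
S10,Items of system Earth,item_count,system,Earth,9,11
S11,Items of system Living,item_count,system,Living,12,14
S12,Items of system Physical,item_count,system,Physical,12,14
S13,Human-coded items,item_count,coding,human,6,14
S14,Machine-coded items,item_count,coding,machine,23,33
S15,Trend items of type Standard,item_count,trend_type,Standard,26,35
S16,Trend items of type Interactive,item_count,trend_type,Interactive,5,10
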