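table_id,file,caption,checksum
T2,paper_table2_cumulative_2024_2043.csv,"Cumulative outcome events among all women, 2024-2043, target participation 50%",443611590
T3,paper_table3_rates_per_100k.csv,"Outcome events per 100,000 screens, 2024-2043, target participation 50%",58028.7
T4,paper_table4_surge_2023_2024.csv,"Absolute and relative change in outcome events from 2023 to 2024, target participation 50%",2852332
T5,paper_table5_stage_2024_2043.csv,"Frequency and proportion of invasive breast cancer and DCIS by stage at diagnosis, 2024-2043",3617732.99
NARR,paper_results_narrative.csv,"Derived figures as printed in the published results narrative (alternate minus referent)",23222295.64
TNM,tnm_stage_map.csv,"Simplified TNM to stage-group lookup used by the staging function",0
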