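dataset_id,study_id,taxon_group,saproxylic,disturbance_type,years_since_disturbance,unlogged_file,logged_file
synthetic_example,synthetic_study,beetles,TRUE,windstorm,3,synthetic_example_unlogged.csv,synthetic_example_logged.csv
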