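# Column schemas for pipeline output CSVs; keys are file globs.
stream.csv: [site_id, tag_id, arrival_s, departure_s]
truth_events.csv: [site_id, day, event_idx, week, start_s, end_s]
truth_membership.csv: [site_id, day, event_idx, tag_id]
truth_ranks.csv: [site_id, week, tag_id, quality, score, latent_rank]
events.csv: [site_id, day, event_idx, start_s, end_s]
membership.csv: [site_id, day, event_idx, tag_id, first_arrival_s]
presence.csv: [site_id, tag_id, week, n_records, present]
roster.csv: [site_id, tag_id]
network_metrics.csv: [site_id, week_id, tag_id, weighted_degree, eigen_centrality, rank_degree, rank_eigen]
consistency.csv: [site_id, habitat, n_individuals, metric, sv_obs, p]
network_repeatability.csv: [metric, subset, R, ci_low, ci_high, ci_level, p, p_method]
network_habitat_comparison.csv: [metric, differs, overlap]
daily_foraging.csv: [site_id, day, n_events, n_visits, clump_arrivals, clump_events, habitat]
event_foraging.csv: [site_id, day, event_idx, n_individuals, duration_s, habitat]
foraging_repeatability.csv: [metric, subset, R, ci_low, ci_high, ci_level, p, p_method]
foraging_habitat_comparison.csv: [metric, differs, overlap]
"model_rank_*.csv": [model, k, logLik, AICc, dAICc, weight, converged]
"model_average_*.csv": [term, estimate, se, weight_sum, n_models]
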