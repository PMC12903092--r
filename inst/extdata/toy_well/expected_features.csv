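name,value
firing_rate_mean,0.045
firing_rate_sd,0.00235702260395516
firing_rate_cov,0.0523782800878924
n_spikes,27
n_active_electrodes,2
isi_mean,17.1992
isi_sd,38.4961157044881
isi_cov,2.23825036655705
eb_rate_mean,0.3
eb_duration_mean,0.283333333333333
eb_duration_sd,0.0351188458428425
eb_duration_cov,0.12394886768062
eb_isi_within_mean,0.0516666666666667
eb_isi_within_sd,0.0164991582276861
eb_isi_within_cov,0.319338546342312
burst_pct_mean,70.0549450549451
burst_pct_sd,12.0441264927379
eb_ibi_mean,9.75
eb_ibi_sd,NA
eb_ibi_cov,NA
spikes_per_burst_mean,6.33333333333333
spikes_per_burst_sd,1.52752523165195
nb_rate,2
nb_duration_mean,0.38
nb_duration_sd,0.0282842712474619
nb_duration_cov,0.0744322927564788
nb_ibi_mean,9.62
nb_ibi_sd,NA
nb_ibi_cov,NA
nb_pct,70.3703703703704
nb_participation_mean,9.375
nb_participation_sd,4.41941738241592
nb_firing_rate_mean,15.9722222222222
nb_firing_rate_sd,4.91046375823992
frag_pct,50
frag_duration_mean,0.15
frag_duration_sd,0.0707106781186548
frag_gap_mean,0.720000000000001
frags_per_main_mean,1
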