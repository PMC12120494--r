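site_id,area
site01,52.528866837290906
site02,41.34383785417647
site03,29.564003673807104
site04,11.102652531245573
site05,9.288899890565148
site06,7.964154230152308
site07,6.3203545608571305
site08,2.4472572654024525
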