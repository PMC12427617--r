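example_id,section,llm_display,wc_display,text
1,llm_high_wc_low,7.59,0.00,"No matter how the job turns out, it’s just a tool, not a goal. It’s primarily about finances and being able to afford things, rather than being part of my identity."
2,llm_high_wc_low,7.85,0.00,"Every now and then, I feel oddly detached, as though I’m witnessing my own life from a distance, fully aware it’s me but feeling as if I’m on the outside looking in."
3,llm_high_wc_low,7.40,0.00,"My lawyer and accountant are puzzled by this situation. This process is typically a standard part of any transaction."
4,llm_low_wc_high,1.00,10.0,"[-] spent the day at the gym and then joined Mom and her parents for a film shoot! It was such an awesome experience!"
5,llm_low_wc_high,1.98,10.0,"On Saturday, we slept in, went to yoga, and played cards—it was such a blast! Overall, it turned out to be a fantastic weekend. Haha!"
6,llm_low_wc_high,3.10,10.0,"We had a fantastic time at a concert tonight! The performances were outstanding, and it was so enjoyable to share the evening together."
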