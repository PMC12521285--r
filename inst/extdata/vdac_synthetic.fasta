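>VDAC3syn synthetic VDAC3 stand-in
MCSTPTYCDLGKGESTVNQHADGESTVNQHAKTKSCSGVEFSTSGHAYTDTGKESTVNQH
KYKVCNYGLIFTQKSTVNQHADGESTVNKHADGESTVNQHKDGESTVNQHADKLKTVNKR
SCFELTAKVSTDAESTHNAGWKGESTVNQHADGESKVNQHADKLCQNNFALGYKSTVNQH
ADGESTVNKHADGESTVNQHADGKSTVNQHADGESTVNQHADGKSTVNCSVAKESTVNQH
ADGESTKNQHADGESTVNQHADKESTVNQHADGESTVNQHADG
>VDAC1syn synthetic VDAC1 stand-in
MDGESTVNQHADGEKTVNQHADGESTVNQKADGESTVNQHADGEKTVNQHADGESTVNQK
ADGESTVNQHADGEKTVNQHADGESTVNQKADGESTVNQHADGEKTVNQHADGESTVNQK
EHINLGCDVDFDIAGPSIRHADGESTVNQHADGEKTVNQHADGESTVNQKADGESTVNQH
ADGEKTVNQHADGESTVNQKADGESTVNQHADGEKTVNQHADGKYQVDPDACFSAKVNQH
ADGESTVNQKADGESTVNQHADGEKTVNQHADGESTVNQHADG
>VDAC2syn synthetic VDAC2 stand-in
MDGESTVNQHADGEKTVNQHADGESTVNQKADGESTVNQHADGESKSCSGVEFSTSGSSN
TDTGKTVNQHADGESTVNQKADGESTVNQHADGEKTVNQHADGESTVNQKADGESTVNQH
ADGEKTVNQHADGESTVNQKADGESTVNQHADGEKTVNQHADGESTVNQKADGESTVNQH
ADGEKTVNQHADGESTVNQKADGESTVNQHADGEKTVNQHADGESTVNQKADGESTVNQH
ADGEKTVNQHADGESTVNQKADGESTVNQHADGEKTVNQHADGESTVNQKADGES
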