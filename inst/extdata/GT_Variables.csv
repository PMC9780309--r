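file,column,type,description
events.csv,t,integer,event start in seconds since T0 midnight (5-s grid)
events.csv,i,character,smaller DID of the dyad
events.csv,j,character,larger DID of the dyad
events.csv,delta,integer,event duration in seconds (positive multiple of 5)
states.csv,i,character,smaller DID of the dyad
states.csv,j,character,larger DID of the dyad
states.csv,slot,integer,5-s slot start time of an active interaction state
schedule.csv,class_id,integer,class number 1-7
schedule.csv,t_start,integer,segment start (seconds since T0 midnight)
schedule.csv,t_end,integer,segment end (half-open)
schedule.csv,label,character,F = free-time (yard) / C = class-time
artifacts.csv,did,character,affected badge DID
artifacts.csv,t_start,integer,injected artifact interval start
artifacts.csv,t_end,integer,injected artifact interval end (half-open)
artifacts.csv,cause,character,"unworn_hub, pile, burst, silent or deaf"
roster.csv,did,character,4-digit badge DID (0xxx child / 1xxx adult / 2xxx RX)
roster.csv,kind,character,"child, adult or rx"
roster.csv,class_id,integer,class of the participant or RX hub
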